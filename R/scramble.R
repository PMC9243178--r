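#' Generate scramble (SCR) control sequences
#'
#' Draws random 20-nt sequences with GC content exactly 50% (ten G/C and
#' ten A/T bases in random arrangement) and rejects any draw for which the
#' genome, on either strand, contains a 20-mer within `max_mismatches`
#' mismatches (PAM-agnostic) — an in-package proxy for "no significant
#' BLAST match". Output is deterministic for a fixed `(n, seed, genome)`.
#'
#' @param n Number of controls to emit.
#' @param seed Integer RNG seed.
#' @param genome A genome tibble.
#' @param params A [design_params()] object (`guide_len`, `max_mismatches`,
#'   `scramble_gc_percent`).
#' @param max_attempts Cap on total draws before giving up (a pathological
#'   genome that rejects everything should fail loudly, not loop forever).
#' @return A tibble with columns `sequence`, `gc_percent`, `seed`; the
#'   attribute `"rejections"` carries an audit tibble of rejected draws and
#'   reasons.
#' @export
generate_scramble <- function(n, seed, genome, params = design_params(),
                              max_attempts = 1000L * n) {
  if (n < 1) rlang::abort("n must be >= 1")
  glen <- params$guide_len
  n_gc <- round(glen * params$scramble_gc_percent / 100)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  emitted <- character(0)
  audit <- list()
  attempts <- 0L
  while (length(emitted) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      rlang::abort(sprintf(
        "scramble generation exceeded %d attempts; genome rejects too many draws",
        max_attempts
      ))
    }
    bases <- character(glen)
    gc_pos <- sample(glen, n_gc)
    bases[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    bases[-gc_pos] <- sample(c("A", "T"), glen - n_gc, replace = TRUE)
    cand <- paste(bases, collapse = "")
    if (cand %in% emitted) {
      audit[[length(audit) + 1L]] <- c(cand, "duplicate draw")
      next
    }
    if (genome_has_near_match(cand, genome, params$max_mismatches)) {
      audit[[length(audit) + 1L]] <- c(cand, sprintf(
        "genomic match within %d mismatches", params$max_mismatches
      ))
      next
    }
    emitted <- c(emitted, cand)
  }
  out <- tibble::tibble(
    sequence = emitted,
    gc_percent = 100 * gc_fraction(emitted),
    seed = as.integer(seed)
  )
  rej <- if (length(audit) > 0) {
    m <- do.call(rbind, audit)
    tibble::tibble(sequence = m[, 1], rejected_reason = m[, 2])
  } else {
    tibble::tibble(sequence = character(), rejected_reason = character())
  }
  attr(out, "rejections") <- rej
  out
}

# TRUE iff `seq20` occurs on either genome strand within max_mm mismatches
# (no PAM requirement).
genome_has_near_match <- function(seq20, genome, max_mm) {
  rc <- revcomp(seq20)
  for (chrom_seq in genome$residues) {
    if (nchar(chrom_seq) < nchar(seq20)) next
    if (any(mismatch_profile(chrom_seq, seq20) <= max_mm)) return(TRUE)
    if (any(mismatch_profile(chrom_seq, rc) <= max_mm)) return(TRUE)
  }
  FALSE
}
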