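#' Load the per-position mismatch weight vector
#'
#' Twenty weights in `[0, 1]`, indexed 1 (PAM-distal) to 20 (PAM-proximal),
#' giving the activity cost of a mismatch at each protospacer position. The
#' packaged default is the experimentally derived SpCas9 position-weight
#' vector in common use by specificity scorers (PAM-proximal "seed"
#' mismatches weigh most).
#'
#' @param path Path to a 20-line TSV (`position`, `weight`); defaults to the
#'   packaged file.
#' @return Numeric vector of length 20.
#' @export
load_mismatch_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mismatch_weights.tsv", package = "promoterguide")
  }
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(position = readr::col_integer(), weight = readr::col_double()),
    progress = FALSE
  )
  if (nrow(tbl) != 20L || !identical(tbl$position, 1:20)) {
    rlang::abort("mismatch weight file must list positions 1..20 in order")
  }
  if (any(tbl$weight < 0 | tbl$weight > 1)) {
    rlang::abort("mismatch weights must lie in [0, 1]")
  }
  tbl$weight
}

#' Find genome-wide near-matches of a guide
#'
#' Returns every genomic 20-mer, on either strand, within `max_mismatches`
#' of the guide and flanked 3' by an NGG PAM (optionally also NAG). The
#' search is an exhaustive vectorised Hamming scan of both strands, so its
#' result is by construction identical to a brute-force scan. Mismatch
#' positions are numbered 1..20 with 1 the PAM-distal end. `N` in the
#' genome never matches.
#'
#' @param guide 20-nt protospacer (A/C/G/T).
#' @param genome A genome tibble.
#' @param params A [design_params()] object (`max_mismatches`).
#' @param include_nag Also accept NAG PAMs at off-target sites.
#' @param exclude Optional one-row tibble/list with `chrom`, `start`,
#'   `strand`: the guide's own (on-target) locus, removed from the hit list.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `sequence` (protospacer-strand 5'→3'), `pam`, `mismatches`,
#'   `mismatch_positions` (list column of integer vectors).
#' @export
find_near_matches <- function(guide, genome, params = design_params(),
                              include_nag = FALSE, exclude = NULL) {
  check_protospacer(guide)
  glen <- nchar(guide)
  max_mm <- params$max_mismatches
  rc_guide <- revcomp(guide)
  pam_re <- if (include_nag) "^[ACGT][AG]G$" else "^[ACGT]GG$"

  hits <- purrr::map(seq_len(nrow(genome)), function(ci) {
    chrom <- genome$seq_id[ci]
    s <- genome$residues[ci]
    L <- nchar(s)
    if (L < glen) return(NULL)

    res <- list()
    # Plus strand: protospacer read directly off the top strand, PAM to the right.
    mm <- mismatch_profile(s, guide)
    cand <- which(mm <= max_mm)
    cand <- cand[cand + glen + 2L <= L]
    if (length(cand) > 0) {
      pam <- substring(s, cand + glen, cand + glen + 2L)
      keep <- grepl(pam_re, pam)
      cand <- cand[keep]; pam <- pam[keep]
      if (length(cand) > 0) {
        seqs <- substring(s, cand, cand + glen - 1L)
        res$plus <- tibble::tibble(
          chrom = chrom, start = cand, end = cand + glen - 1L, strand = "+",
          sequence = seqs, pam = pam, mismatches = mm[cand],
          mismatch_positions = purrr::map(seqs, mismatch_positions, b = guide)
        )
      }
    }
    # Minus strand: a protospacer at top coords [i, i+19] is
    # revcomp(top[i..i+19]); comparing revcomp(guide) against the top strand
    # gives the same mismatch count. PAM sits to the LEFT in top coords.
    mm <- mismatch_profile(s, rc_guide)
    cand <- which(mm <= max_mm)
    cand <- cand[cand - 3L >= 1L]
    if (length(cand) > 0) {
      pam <- revcomp(substring(s, cand - 3L, cand - 1L))
      keep <- grepl(pam_re, pam)
      cand <- cand[keep]; pam <- pam[keep]
      if (length(cand) > 0) {
        seqs <- revcomp(substring(s, cand, cand + glen - 1L))
        res$minus <- tibble::tibble(
          chrom = chrom, start = cand, end = cand + glen - 1L, strand = "-",
          sequence = seqs, pam = pam, mismatches = mm[cand],
          mismatch_positions = purrr::map(seqs, mismatch_positions, b = guide)
        )
      }
    }
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), sequence = character(), pam = character(),
      mismatches = integer(), mismatch_positions = list()
    )
  }
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out$mismatches <- as.integer(out$mismatches)
  if (!is.null(exclude)) {
    own <- out$chrom == exclude$chrom & out$start == exclude$start &
      out$strand == exclude$strand
    out <- out[!own, , drop = FALSE]
  }
  out
}

#' Per-site off-target penalty
#'
#' The penalty of one near-match site is
#' `100 * prod(1 - W[p]) * D / m^2` over its mismatch positions `p`, where
#' `m` is the mismatch count and `D = 1 / (((19 - dbar)/19) * 4 + 1)` damps
#' clustered mismatches via the mean pairwise distance `dbar` between
#' mismatch positions (`D = 1` for fewer than two mismatches). A perfect
#' match scores 100; heavily weighted, spread-out mismatches drive the
#' penalty toward 0.
#'
#' @param guide The 20-nt guide.
#' @param hit A one-row hit (tibble row or list) with `sequence` and
#'   `mismatch_positions`.
#' @param weights Mismatch weight vector (see [load_mismatch_weights()]).
#' @return Penalty in `[0, 100]`.
#' @export
hit_penalty <- function(guide, hit, weights = load_mismatch_weights()) {
  mmp <- hit$mismatch_positions
  if (is.list(mmp)) mmp <- mmp[[1]]
  seq <- if (is.list(hit$sequence)) hit$sequence[[1]] else hit$sequence
  if (!identical(as.integer(sort(mmp)), as.integer(mismatch_positions(guide, seq)))) {
    rlang::abort("mismatch_positions inconsistent with guide vs. matched sequence")
  }
  penalty_from_positions(mmp, weights)
}

penalty_from_positions <- function(mmp, weights) {
  m <- length(mmp)
  if (m == 0) return(100)
  prod_term <- prod(1 - weights[mmp])
  D <- if (m >= 2) {
    dbar <- mean(stats::dist(mmp))
    1 / (((19 - dbar) / 19) * 4 + 1)
  } else 1
  100 * prod_term * D / m^2
}

#' Aggregate specificity score of a guide
#'
#' `100 * 100 / (100 + sum of per-site penalties)` over the guide's
#' off-target hits (its own on-target locus excluded). 100 means no
#' near-match anywhere else in the genome; every additional hit strictly
#' lowers the score.
#'
#' @param guide The 20-nt guide.
#' @param hits Hit tibble from [find_near_matches()] (on-target excluded).
#' @param weights Mismatch weight vector.
#' @return Score in `(0, 100]`.
#' @export
specificity_score <- function(guide, hits, weights = load_mismatch_weights()) {
  if (nrow(hits) == 0) return(100)
  penalties <- purrr::map_dbl(hits$mismatch_positions, penalty_from_positions,
                              weights = weights)
  100 * 100 / (100 + sum(penalties))
}
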