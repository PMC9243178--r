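#' Enumerate PAM-flanked protospacer candidates in a promoter window
#'
#' Scans both strands of the window for every `guide_len`-mer whose entire
#' protospacer lies inside the window and whose immediately 3'-adjacent
#' PAM (default NGG) is present in the genome; the PAM itself may extend up
#' to its own length outside the window. Candidates overlapping an `N` (in
#' protospacer or PAM) are dropped. Protospacers are reported 5'→3' on
#' their own strand. TSS offsets record how far upstream of the TSS the
#' protospacer base nearest (`tss_offset_near`) and farthest
#' (`tss_offset_far`) from the TSS lie.
#'
#' @param window A one-row promoter-window tibble (see [promoter_window()]).
#' @param genome A genome tibble (see [read_genome_fasta()]).
#' @param params A [design_params()] object.
#' @return A tibble of unscored candidates with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `protospacer`, `pam`, `tss_offset_near`,
#'   `tss_offset_far`. Zero rows when the window has no PAM-adjacent site.
#' @export
enumerate_candidates <- function(window, genome, params = design_params()) {
  stopifnot(nrow(window) == 1)
  chrom_seq <- genome$residues[match(window$chrom, genome$seq_id)]
  if (is.na(chrom_seq)) {
    rlang::abort(sprintf("chromosome %s not present in genome", window$chrom))
  }
  chrom_len <- nchar(chrom_seq)
  if (window$start < 1L || window$end > chrom_len) {
    rlang::abort("window outside genome bounds")
  }
  glen <- params$guide_len
  plen <- nchar(params$pam_pattern)
  pam_re <- paste0("^", iupac_to_regex(params$pam_pattern), "$")
  empty <- tibble::tibble(
    gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    protospacer = character(), pam = character(),
    tss_offset_near = integer(), tss_offset_far = integer()
  )
  if (window$end - window$start + 1L < glen) return(empty)

  starts <- window$start:(window$end - glen + 1L)

  # Plus-strand candidates: PAM immediately 3' (to the right) of the 20-mer.
  plus_ok <- starts + glen + plen - 1L <= chrom_len
  sp <- starts[plus_ok]
  plus <- tibble::tibble(
    start = sp,
    end = sp + glen - 1L,
    strand = "+",
    protospacer = substring(chrom_seq, sp, sp + glen - 1L),
    pam = substring(chrom_seq, sp + glen, sp + glen + plen - 1L)
  )
  plus <- plus[grepl(pam_re, plus$pam) & !grepl("N", plus$protospacer, fixed = TRUE), ]

  # Minus-strand candidates: protospacer is the reverse complement of the
  # top-strand 20-mer; its PAM sits immediately to the LEFT in top-strand
  # coordinates.
  minus_ok <- starts - plen >= 1L
  sm <- starts[minus_ok]
  minus <- tibble::tibble(
    start = sm,
    end = sm + glen - 1L,
    strand = "-",
    protospacer = revcomp(substring(chrom_seq, sm, sm + glen - 1L)),
    pam = revcomp(substring(chrom_seq, sm - plen, sm - 1L))
  )
  minus <- minus[grepl(pam_re, minus$pam) & !grepl("N", minus$protospacer, fixed = TRUE), ]

  out <- dplyr::bind_rows(plus, minus)
  if (nrow(out) == 0) return(empty)
  tss <- window$tss_position
  out$tss_offset_near <- pmin(abs(out$start - tss), abs(out$end - tss))
  out$tss_offset_far <- pmax(abs(out$start - tss), abs(out$end - tss))
  out <- dplyr::arrange(out, .data$start, .data$strand)
  tibble::tibble(
    gene_id = window$gene_id, chrom = window$chrom,
    start = as.integer(out$start), end = as.integer(out$end),
    strand = out$strand, protospacer = out$protospacer, pam = out$pam,
    tss_offset_near = as.integer(out$tss_offset_near),
    tss_offset_far = as.integer(out$tss_offset_far)
  )
}

#' 30-mer scoring context for candidate guides
#'
#' Extracts, strand-aware, the 30-mer used by [on_target_score()]: 4 nt of
#' 5' flank, the 20-nt protospacer, the 3-nt PAM, and 3 nt of 3' flank.
#' Candidates whose context would run past a chromosome end get `NA`.
#'
#' @param guides A candidate tibble (see [enumerate_candidates()]).
#' @param genome A genome tibble.
#' @return `guides` with an added `context30` column.
#' @export
scoring_context <- function(guides, genome) {
  chrom_seq <- genome$residues[match(guides$chrom, genome$seq_id)]
  chrom_len <- nchar(chrom_seq)
  up <- 4L; down <- 3L; plen <- 3L
  ctx <- ifelse(
    guides$strand == "+",
    ifelse(guides$start - up >= 1L & guides$end + plen + down <= chrom_len,
           substring(chrom_seq, guides$start - up, guides$end + plen + down), NA),
    ifelse(guides$start - plen - down >= 1L & guides$end + up <= chrom_len,
           revcomp(substring(chrom_seq, guides$start - plen - down, guides$end + up)), NA)
  )
  ctx[!is.na(ctx) & grepl("N", ctx, fixed = TRUE)] <- NA
  guides$context30 <- ctx
  guides
}

#' Filter scored candidates by the score thresholds and rank them
#'
#' In strict mode (the default) only candidates with on-target AND
#' specificity scores strictly above the thresholds are kept; in permissive
#' mode all candidates are kept and a logical `pass` column records the
#' threshold test. Ranking (within each gene) is by on-target score
#' descending, ties broken by specificity score descending, then smaller
#' `tss_offset_near`, then protospacer lexicographic order — a total,
#' reproducible order.
#'
#' @param candidates A scored candidate tibble (`on_score`, `spec_score` set).
#' @param params A [design_params()] object.
#' @param mode `"strict"` or `"permissive"`.
#' @return The filtered, ranked tibble.
#' @export
filter_and_rank <- function(candidates, params = design_params(),
                            mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (!all(c("on_score", "spec_score") %in% names(candidates)) ||
      anyNA(candidates$on_score) || anyNA(candidates$spec_score)) {
    rlang::abort("all candidates must be scored before filtering")
  }
  pass <- candidates$on_score > params$min_on_score &
    candidates$spec_score > params$min_spec_score
  out <- if (mode == "strict") {
    candidates[pass, , drop = FALSE]
  } else {
    dplyr::mutate(candidates, pass = pass)
  }
  gene_levels <- unique(candidates$gene_id)
  dplyr::arrange(
    out,
    factor(.data$gene_id, levels = gene_levels),
    dplyr::desc(.data$on_score),
    dplyr::desc(.data$spec_score),
    .data$tss_offset_near,
    .data$protospacer
  )
}

#' Format a guide label as `XX_<protospacer>`
#'
#' `XX` is the on-target score rounded half-up to an integer, zero-padded
#' to two digits and clamped at 99 so the prefix is always exactly two
#' characters.
#'
#' @param on_score Numeric vector of on-target scores in `[0, 100]`.
#' @param protospacer Character vector of 20-nt protospacers.
#' @return Character vector of labels.
#' @export
#' @examples
#' format_guide_label(87.4, "GATTACAGATTACAGATTAC")
format_guide_label <- function(on_score, protospacer) {
  xx <- pmin(99L, as.integer(floor(on_score + 0.5)))
  sprintf("%02d_%s", xx, protospacer)
}
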