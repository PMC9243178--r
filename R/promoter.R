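#' Design parameters for promoter-specific sgRNA selection
#'
#' Bundles the tunable knobs of the design procedure. Defaults encode the
#' published rule set: candidates are drawn from the region 50 to 400 bp
#' upstream of the representative TSS, protospacers are 20 nt flanked by an
#' NGG PAM, and strict filtering keeps guides with on-target and specificity
#' scores above 50. `max_mismatches` bounds the genome-wide near-match
#' search used both for specificity scoring and for vetting scramble
#' controls.
#'
#' @param near Closest allowed upstream distance of the window, in bp.
#' @param far Farthest allowed upstream distance of the window, in bp.
#' @param guide_len Protospacer length in nt.
#' @param pam_pattern PAM as an IUPAC string immediately 3' of the protospacer.
#' @param min_on_score Strict-mode lower bound (exclusive) on the on-target score.
#' @param min_spec_score Strict-mode lower bound (exclusive) on the specificity score.
#' @param max_mismatches Mismatch radius of the off-target search.
#' @param scramble_gc_percent Required GC percentage of scramble controls.
#' @return A list of class `design_params`.
#' @export
design_params <- function(near = 50L, far = 400L, guide_len = 20L,
                          pam_pattern = "NGG", min_on_score = 50,
                          min_spec_score = 50, max_mismatches = 4L,
                          scramble_gc_percent = 50) {
  near <- as.integer(near); far <- as.integer(far); guide_len <- as.integer(guide_len)
  if (!(near > 0L && far > near)) rlang::abort("need 0 < near < far")
  if (guide_len < 1L) rlang::abort("guide_len must be >= 1")
  if (far - near + 1L < guide_len) {
    rlang::abort("window shorter than guide_len: no candidate can fit")
  }
  if (min_on_score < 0 || min_on_score > 100 || min_spec_score < 0 || min_spec_score > 100) {
    rlang::abort("score thresholds must lie in [0, 100]")
  }
  structure(
    list(
      near = near, far = far, guide_len = guide_len,
      pam_pattern = toupper(pam_pattern),
      min_on_score = min_on_score, min_spec_score = min_spec_score,
      max_mismatches = as.integer(max_mismatches),
      scramble_gc_percent = scramble_gc_percent
    ),
    class = "design_params"
  )
}

#' Select the representative TSS for one gene
#'
#' Given this gene's stage-resolved representative TSS records, returns the
#' adult record when present, otherwise the embryonic one — adult expression
#' is what promoter activation is usually aimed at, so the adult TSS takes
#' preference.
#'
#' @param records A TSS tibble (rows for a single gene).
#' @return A one-row TSS tibble.
#' @export
select_representative_tss <- function(records) {
  if (nrow(records) == 0) rlang::abort("no TSS records supplied")
  if (dplyr::n_distinct(records$gene_id) != 1) {
    rlang::abort("records span multiple gene_ids")
  }
  if (anyDuplicated(records$stage)) {
    rlang::abort(sprintf(
      "gene %s has multiple records for one stage; representative TSS is ambiguous",
      records$gene_id[1]
    ))
  }
  adult <- dplyr::filter(records, .data$stage == "adult")
  if (nrow(adult) == 1) adult else dplyr::filter(records, .data$stage == "embryonic")
}

#' Compute the upstream promoter window for a TSS
#'
#' The window covers the bases `near`..`far` bp strictly upstream of the TSS
#' on the gene's strand (TSS itself is offset 0). Coordinates are 1-based
#' inclusive. Windows running off a chromosome end are clamped with a
#' warning; a window falling entirely outside the chromosome is an error.
#'
#' @param tss A one-row TSS tibble (see [select_representative_tss()]).
#' @param params A [design_params()] object.
#' @param chrom_length Length of the TSS's chromosome in bp.
#' @return A one-row tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss_position`, `clamped`.
#' @export
#' @examples
#' tss <- tibble::tibble(gene_id = "g1", public_name = "g1", chrom = "chrI",
#'                       position = 1000L, strand = "+", stage = "adult")
#' promoter_window(tss, design_params(), chrom_length = 5000L)
promoter_window <- function(tss, params = design_params(), chrom_length) {
  stopifnot(nrow(tss) == 1)
  pos <- tss$position
  chrom_length <- as.integer(chrom_length)
  if (pos > chrom_length) {
    rlang::abort(sprintf("gene %s: TSS position %d beyond chromosome end (%d)",
                         tss$gene_id, pos, chrom_length))
  }
  if (tss$strand == "+") {
    raw_start <- pos - params$far
    raw_end <- pos - params$near
  } else {
    raw_start <- pos + params$near
    raw_end <- pos + params$far
  }
  start <- max(1L, raw_start)
  end <- min(chrom_length, raw_end)
  if (start > end) {
    rlang::abort(sprintf(
      "gene %s: promoter window [%d, %d] lies entirely outside chromosome %s",
      tss$gene_id, raw_start, raw_end, tss$chrom
    ))
  }
  clamped <- start != raw_start || end != raw_end
  if (clamped) {
    rlang::warn(sprintf("gene %s: promoter window clamped to chromosome bounds", tss$gene_id))
  }
  tibble::tibble(
    gene_id = tss$gene_id,
    chrom = tss$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = tss$strand,
    tss_position = as.integer(pos),
    clamped = clamped
  )
}
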