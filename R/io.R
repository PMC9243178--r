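#' Read a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a genome table. Residues are
#' uppercased and RNA `U` is normalised to `T`; any character outside
#' A/C/G/T/N is an error naming the record and offset. Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id`, `residues`, `length` (one row per
#'   record).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrI", "acgtacgt"), fa)
#' read_genome_fasta(fa)
read_genome_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) rlang::abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate seq_id in %s: %s", path, paste(unique(dup), collapse = ", ")))
  }
  residues <- purrr::map2_chr(
    as.character(set), ids,
    function(res, id) normalize_residues(res, what = sprintf("record '%s'", id))
  )
  tibble::tibble(
    seq_id = ids,
    residues = unname(residues),
    length = nchar(residues)
  )
}

#' Write a genome table to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param genome A genome tibble (`seq_id`, `residues`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::BStringSet(stats::setNames(genome$residues, genome$seq_id))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

tss_table_cols <- c("gene_id", "public_name", "chrom", "position", "strand", "stage")

#' Read a representative-TSS table
#'
#' Expects a tab-separated file with header columns `gene_id`, `public_name`,
#' `chrom`, `position` (1-based TSS coordinate), `strand` (`+`/`-`) and
#' `stage` (`embryonic` or `adult`). Each gene may carry at most one
#' representative TSS per stage; a duplicated (gene_id, stage) pair is a
#' parse-time error because the downstream stage-preference rule would be
#' ambiguous.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per TSS record.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(tss_table_cols, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(sprintf("TSS table missing column(s): %s", paste(missing, collapse = ", ")))
  }
  tbl <- dplyr::select(tbl, dplyr::all_of(tss_table_cols))
  pos <- suppressWarnings(as.integer(tbl$position))
  num <- suppressWarnings(as.numeric(tbl$position))
  bad <- which(is.na(pos) | is.na(num) | num != pos)
  if (length(bad) > 0) {
    rlang::abort(sprintf("non-integer TSS position in row %d: '%s'", bad[1], tbl$position[bad[1]]))
  }
  tbl$position <- pos
  if (any(tbl$position < 1L)) {
    rlang::abort("TSS positions must be >= 1 (1-based coordinates)")
  }
  bad_strand <- setdiff(unique(tbl$strand), c("+", "-"))
  if (length(bad_strand) > 0) {
    rlang::abort(sprintf("invalid strand value(s): %s", paste(bad_strand, collapse = ", ")))
  }
  bad_stage <- setdiff(unique(tbl$stage), c("embryonic", "adult"))
  if (length(bad_stage) > 0) {
    rlang::abort(sprintf(
      "invalid stage value(s): %s (must be 'embryonic' or 'adult')",
      paste(bad_stage, collapse = ", ")
    ))
  }
  key <- paste(tbl$gene_id, tbl$stage)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    rlang::abort(sprintf("duplicate (gene_id, stage) record: %s", d))
  }
  tbl
}

guide_library_cols <- c(
  "gene_id", "public_name", "chrom", "start", "end", "strand",
  "protospacer", "pam", "tss_offset_near", "tss_offset_far",
  "on_score", "spec_score", "label"
)

#' Write a ranked guide library to TSV (with optional FASTA sidecar)
#'
#' Rows are grouped by gene and, within each gene, sorted by on-target score
#' descending. Scores are serialised at 4 decimal places so that re-parsing
#' the file reproduces every field exactly.
#'
#' @param guides A guide tibble (see [enumerate_candidates()] /
#'   [run_design_pipeline()]).
#' @param path Output TSV path.
#' @param fasta Optional path for a FASTA sidecar with one entry per guide
#'   (id `gene_id|label`); `NULL` (default) skips it.
#' @return `path`, invisibly.
#' @export
write_guide_library <- function(guides, path, fasta = NULL) {
  out <- dplyr::select(guides, dplyr::all_of(guide_library_cols))
  out <- dplyr::arrange(out, factor(.data$gene_id, levels = unique(.data$gene_id)),
                        dplyr::desc(.data$on_score))
  out$on_score <- round(out$on_score, 4)
  out$spec_score <- round(out$spec_score, 4)
  ser <- out
  ser$on_score <- sprintf("%.4f", ser$on_score)
  ser$spec_score <- sprintf("%.4f", ser$spec_score)
  readr::write_tsv(ser, path, progress = FALSE)
  if (!is.null(fasta)) {
    set <- Biostrings::BStringSet(stats::setNames(
      out$protospacer, paste(out$gene_id, out$label, sep = "|")
    ))
    Biostrings::writeXStringSet(set, filepath = fasta, width = 60L)
  }
  invisible(path)
}

#' Read a guide library TSV written by [write_guide_library()]
#'
#' @param path Path to the TSV file.
#' @return A guide tibble.
#' @export
read_guide_library <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      public_name = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      protospacer = readr::col_character(),
      pam = readr::col_character(),
      tss_offset_near = readr::col_integer(),
      tss_offset_far = readr::col_integer(),
      on_score = readr::col_double(),
      spec_score = readr::col_double(),
      label = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Export promoter windows as BED6
#'
#' Writes 0-based half-open intervals (`name` = gene_id, `score` = 0) for
#' genome-browser use.
#'
#' @param windows A promoter-window tibble (see [promoter_window()]).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- tibble::tibble(
    chrom = windows$chrom,
    chromStart = windows$start - 1L,
    chromEnd = windows$end,
    name = windows$gene_id,
    score = 0L,
    strand = windows$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
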