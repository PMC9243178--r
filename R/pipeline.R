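#' Run the full promoter-specific sgRNA design pipeline
#'
#' For every gene in the TSS table: choose the representative TSS (adult
#' preferred over embryonic), compute the -`near`..-`far` bp upstream
#' window, enumerate NGG-flanked 20-mers on both strands, score each with
#' the on-target model and the genome-wide specificity score (the guide's
#' own locus excluded), filter per mode, rank, and label. A run report
#' accounts for every gene with a status and, where applicable, a skip
#' reason (`WINDOW_ERROR`, `WINDOW_CLAMPED_EMPTY`, `NO_CANDIDATES`,
#' `ALL_FILTERED`).
#'
#' @param genome A genome tibble (see [read_genome_fasta()]).
#' @param tss_table A TSS tibble (see [read_tss_table()]).
#' @param params A [design_params()] object.
#' @param mode `"strict"` (keep only guides with both scores above
#'   threshold) or `"permissive"` (keep all, flag `pass`).
#' @param stages `"preferred"` (one window per gene, adult preferred) or
#'   `"both"` (design separately for every stage present).
#' @param model On-target model (see [load_on_target_model()]).
#' @param mismatch_weights Mismatch weight vector for specificity scoring.
#' @return An object of class `sg_design`: list with `guides` (ranked,
#'   labelled tibble), `report` (per-gene tibble), `params`, `mode`.
#' @export
run_design_pipeline <- function(genome, tss_table, params = design_params(),
                                mode = c("strict", "permissive"),
                                stages = c("preferred", "both"),
                                model = load_on_target_model(),
                                mismatch_weights = load_mismatch_weights()) {
  mode <- match.arg(mode)
  stages <- match.arg(stages)
  gene_ids <- unique(tss_table$gene_id)
  chrom_len <- stats::setNames(genome$length, genome$seq_id)

  guides <- list()
  report <- list()
  for (gid in gene_ids) {
    recs <- tss_table[tss_table$gene_id == gid, , drop = FALSE]
    chosen <- if (stages == "preferred") {
      list(select_representative_tss(recs))
    } else {
      purrr::map(seq_len(nrow(recs)), ~recs[.x, , drop = FALSE])
    }
    for (tss in chosen) {
      status <- "OK"; reason <- NA_character_; n_cand <- 0L; n_kept <- 0L
      g <- NULL
      win <- tryCatch(
        suppressWarnings(
          promoter_window(tss, params, chrom_length = chrom_len[[tss$chrom]])
        ),
        error = function(e) NULL
      )
      if (is.null(win)) {
        status <- "SKIPPED"; reason <- "WINDOW_ERROR"
      } else if (win$end - win$start + 1L < params$guide_len) {
        status <- "SKIPPED"; reason <- "WINDOW_CLAMPED_EMPTY"
      } else {
        cand <- enumerate_candidates(win, genome, params)
        cand <- scoring_context(cand, genome)
        cand <- cand[!is.na(cand$context30), , drop = FALSE]
        n_cand <- nrow(cand)
        if (n_cand == 0L) {
          status <- "SKIPPED"; reason <- "NO_CANDIDATES"
        } else {
          cand$on_score <- on_target_score(cand$context30, model)
          cand$spec_score <- purrr::map_dbl(seq_len(n_cand), function(i) {
            hits <- find_near_matches(
              cand$protospacer[i], genome, params,
              exclude = list(chrom = cand$chrom[i], start = cand$start[i],
                             strand = cand$strand[i])
            )
            specificity_score(cand$protospacer[i], hits, mismatch_weights)
          })
          kept <- filter_and_rank(cand, params, mode)
          n_kept <- nrow(kept)
          if (n_kept == 0L) {
            status <- "SKIPPED"; reason <- "ALL_FILTERED"
          } else {
            kept$label <- format_guide_label(kept$on_score, kept$protospacer)
            kept$public_name <- tss$public_name
            kept$stage <- tss$stage
            kept$context30 <- NULL
            g <- kept
          }
        }
      }
      if (!is.null(g)) guides[[length(guides) + 1L]] <- g
      report[[length(report) + 1L]] <- tibble::tibble(
        gene_id = gid, stage = tss$stage, status = status, reason = reason,
        n_candidates = n_cand, n_retained = n_kept
      )
    }
  }
  guide_cols <- c(guide_library_cols, "stage",
                  if (mode == "permissive") "pass")
  guides <- if (length(guides) > 0) {
    dplyr::select(dplyr::bind_rows(guides), dplyr::all_of(guide_cols))
  } else {
    empty <- stats::setNames(
      rep(list(character(0)), length(guide_cols)), guide_cols
    )
    empty <- tibble::as_tibble(empty)
    for (col in c("start", "end", "tss_offset_near", "tss_offset_far")) {
      empty[[col]] <- integer(0)
    }
    for (col in c("on_score", "spec_score")) empty[[col]] <- numeric(0)
    empty
  }
  structure(
    list(guides = guides, report = dplyr::bind_rows(report),
         params = params, mode = mode),
    class = "sg_design"
  )
}

#' @export
print.sg_design <- function(x, ...) {
  cat(sprintf(
    "<sg_design> %d guide(s) across %d gene(s) [%s mode]\n",
    nrow(x$guides), dplyr::n_distinct(x$report$gene_id), x$mode
  ))
  skipped <- x$report[x$report$status == "SKIPPED", ]
  if (nrow(skipped) > 0) {
    cat(sprintf("  skipped: %s\n",
                paste(sprintf("%s (%s)", skipped$gene_id, skipped$reason),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a design run into its per-guide table
#'
#' @param x An `sg_design` object.
#' @param ... Unused.
#' @return The ranked guide tibble.
#' @exportS3Method generics::tidy
tidy.sg_design <- function(x, ...) x$guides

#' One-row summary of a design run
#'
#' @param x An `sg_design` object.
#' @param ... Unused.
#' @return A one-row tibble: gene counts, guide count, score medians.
#' @exportS3Method generics::glance
glance.sg_design <- function(x, ...) {
  tibble::tibble(
    n_genes = dplyr::n_distinct(x$report$gene_id),
    n_genes_with_guides = dplyr::n_distinct(x$guides$gene_id),
    n_guides = nrow(x$guides),
    median_on_score = stats::median(x$guides$on_score),
    median_spec_score = stats::median(x$guides$spec_score),
    mode = x$mode
  )
}

#' Score scatter plot of a design run
#'
#' On-target vs. specificity score per retained guide, with the filter
#' thresholds drawn as dashed lines.
#'
#' @param object An `sg_design` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sg_design <- function(object, ...) {
  ggplot2::ggplot(object$guides,
                  ggplot2::aes(x = .data$on_score, y = .data$spec_score,
                               colour = .data$gene_id)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$params$min_on_score, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$params$min_spec_score, linetype = "dashed") +
    ggplot2::labs(x = "on-target score", y = "specificity score",
                  colour = "gene") +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot guide placement relative to the TSS
#'
#' Shows each retained guide as a horizontal segment over its upstream
#' offset range, per gene, coloured by on-target score.
#'
#' @param design An `sg_design` object.
#' @return A ggplot object.
#' @export
plot_guide_positions <- function(design) {
  g <- design$guides
  ggplot2::ggplot(g, ggplot2::aes(y = .data$gene_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = -.data$tss_offset_far, xend = -.data$tss_offset_near,
                   yend = .data$gene_id, colour = .data$on_score),
      linewidth = 2
    ) +
    ggplot2::labs(x = "position relative to TSS (bp)", y = NULL,
                  colour = "on-target\nscore") +
    ggplot2::theme_minimal()
}
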