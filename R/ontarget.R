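#' Load a position-weight on-target model
#'
#' The model is a logistic regression over sequence features of a 30-mer
#' context: 4 nt of upstream flank, the 20-nt protospacer (positions 5-24;
#' protospacer position 20, the PAM-proximal end, is 30-mer position 24),
#' the 3-nt PAM (25-27), and 3 nt of downstream flank. Features are single
#' nucleotides or dinucleotides anchored at a 30-mer position. The score is
#' `100 * logistic(intercept + sum of matched weights)`, so it always lies
#' in (0, 100).
#'
#' The packaged default table carries this package's own weight set, built
#' from the qualitative sequence preferences reported for SpCas9 activity
#' models (e.g. a purine, especially G, favoured at the PAM-proximal
#' protospacer end, pyrimidine runs disfavoured). It is a documented
#' stand-in, not a re-fit of any published model; any table with the same
#' layout can be swapped in.
#'
#' @param path Path to a weight TSV (`position`, `token`, `weight`; the row
#'   with position 0 and token `(intercept)` is the intercept). Defaults to
#'   the packaged table.
#' @return A list of class `on_target_model` with elements `intercept` and
#'   `weights` (tibble).
#' @export
load_on_target_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "on_target_weights.tsv", package = "promoterguide")
  }
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      position = readr::col_integer(),
      token = readr::col_character(),
      weight = readr::col_double()
    ),
    progress = FALSE
  )
  int_row <- tbl$position == 0L & tbl$token == "(intercept)"
  intercept <- if (any(int_row)) tbl$weight[int_row][1] else 0
  weights <- tbl[!int_row, ]
  bad <- weights$position < 1L | weights$position + nchar(weights$token) - 1L > 30L
  if (any(bad)) rlang::abort("weight table has features outside the 30-mer layout")
  structure(list(intercept = intercept, weights = weights), class = "on_target_model")
}

#' Build an on-target model from explicit weights
#'
#' Mostly useful for testing and for swapping in alternative weight sets.
#'
#' @param weights A tibble with columns `position`, `token`, `weight`
#'   (may have zero rows).
#' @param intercept Intercept of the logistic model.
#' @return An `on_target_model`.
#' @export
on_target_model <- function(weights = tibble::tibble(position = integer(),
                                                     token = character(),
                                                     weight = double()),
                            intercept = 0) {
  structure(list(intercept = intercept, weights = tibble::as_tibble(weights)),
            class = "on_target_model")
}

#' Score 30-mer contexts with an on-target model
#'
#' @param context30 Character vector of 30-nt contexts (A/C/G/T only; the
#'   protospacer occupies positions 5-24).
#' @param model An `on_target_model`; defaults to the packaged table.
#' @return Numeric vector of scores in (0, 100).
#' @export
#' @examples
#' on_target_score(strrep("A", 30), on_target_model())  # 50 under a null model
on_target_score <- function(context30, model = load_on_target_model()) {
  if (length(context30) == 0) return(numeric(0))
  if (any(nchar(context30) != 30L)) {
    rlang::abort("every scoring context must be exactly 30 nt")
  }
  if (any(stringr::str_detect(context30, "[^ACGT]"))) {
    rlang::abort("scoring context must contain only A/C/G/T (N-containing candidates are dropped upstream)")
  }
  w <- model$weights
  lin <- rep(model$intercept, length(context30))
  for (i in seq_len(nrow(w))) {
    p <- w$position[i]
    tok <- w$token[i]
    hit <- substr(context30, p, p + nchar(tok) - 1L) == tok
    lin <- lin + ifelse(hit, w$weight[i], 0)
  }
  100 * stats::plogis(lin)
}
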