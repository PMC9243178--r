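#' Load the restriction-enzyme registry
#'
#' Each enzyme carries its recognition sequence and its cut geometry as the
#' number of top- and bottom-strand bases (counted from the recognition
#' start on the enzyme's own reading frame) lying 5' of the cut; type IIS
#' enzymes cut downstream of the recognition, so their offsets exceed the
#' recognition length. The registry ships the standard definitions for the
#' enzymes used in sgRNA-vector construction (EcoRI, HindIII, PstI, XbaI,
#' SpeI, BsaI, BbsI).
#'
#' @param path Optional path to an alternative registry TSV (`name`,
#'   `recognition`, `cut_top`, `cut_bottom`, `class`).
#' @return A tibble registry.
#' @export
load_enzyme_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "promoterguide")
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      recognition = readr::col_character(),
      cut_top = readr::col_integer(),
      cut_bottom = readr::col_integer(),
      class = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Look up one enzyme from the registry
#'
#' @param name Enzyme name, e.g. `"EcoRI"`.
#' @param registry A registry tibble (see [load_enzyme_registry()]).
#' @return A one-row list with the enzyme's fields.
#' @export
get_enzyme <- function(name, registry = load_enzyme_registry()) {
  i <- match(name, registry$name)
  if (is.na(i)) rlang::abort(sprintf("enzyme %s not registered", name))
  as.list(registry[i, ])
}
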