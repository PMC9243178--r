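#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. Accepts uppercase A/C/G/T/N.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("GATTACA", "ACGT"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' GC content of DNA strings
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  stringr::str_count(x, "[GC]") / nchar(x)
}

# Validate and normalise a residue string: uppercase, U -> T, only A/C/G/T/N.
# `what` names the sequence in error messages.
normalize_residues <- function(res, what = "sequence") {
  res <- chartr("u", "U", toupper(res))
  res <- chartr("U", "T", res)
  bad <- stringr::str_locate(res, "[^ACGTN]")[, "start"]
  if (!is.na(bad)) {
    rlang::abort(sprintf(
      "illegal residue '%s' in %s at offset %d",
      substr(res, bad, bad), what, bad
    ))
  }
  res
}

# Hamming mismatch count profile of `pattern` against every k-mer start of
# `subject` (both plain uppercase strings). Returns an integer vector of
# length nchar(subject) - k + 1; position i is the number of mismatching
# bases between pattern and substr(subject, i, i + k - 1). N mismatches
# everything. Fully vectorised over subject positions.
mismatch_profile <- function(subject, pattern) {
  k <- nchar(pattern)
  n <- nchar(subject) - k + 1L
  if (n < 1L) return(integer(0))
  s <- charToRaw(subject)
  p <- charToRaw(pattern)
  mm <- integer(n)
  for (i in seq_len(k)) {
    mm <- mm + (s[i:(n + i - 1L)] != p[i])
  }
  mm
}

# Per-position character equality between two equal-length strings; returns
# integer positions (1-based) that differ.
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

check_protospacer <- function(guide, arg = "guide") {
  if (!is.character(guide) || length(guide) != 1L || is.na(guide)) {
    rlang::abort(sprintf("`%s` must be a single DNA string", arg))
  }
  if (nchar(guide) != 20L) {
    rlang::abort(sprintf("`%s` must be 20 nt, got %d", arg, nchar(guide)))
  }
  if (stringr::str_detect(guide, "[^ACGT]")) {
    rlang::abort(sprintf("`%s` must contain only A/C/G/T", arg))
  }
  invisible(guide)
}

# IUPAC code -> regex character class (DNA).
iupac_to_regex <- function(pattern) {
  map <- c(
    A = "A", C = "C", G = "G", T = "T",
    R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
    K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
    H = "[ACT]", V = "[ACG]", N = "[ACGT]"
  )
  codes <- strsplit(toupper(pattern), "")[[1]]
  unknown <- setdiff(codes, names(map))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown IUPAC code(s): %s", paste(unknown, collapse = ", ")))
  }
  paste(map[codes], collapse = "")
}
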