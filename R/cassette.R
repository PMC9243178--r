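#' Construct a DNA vector molecule
#'
#' A light container for circular or linear double-stranded DNA with an
#' optional feature table, used by the cloning simulator.
#'
#' @param name Molecule name.
#' @param residues Top-strand sequence 5'→3' (A/C/G/T/N, any case).
#' @param topology `"circular"` or `"linear"`.
#' @param features Optional tibble with columns `label`, `start`, `end`,
#'   `strand` (1-based inclusive; may wrap the origin when circular).
#' @return An object of class `vector_sequence`.
#' @export
vector_sequence <- function(name, residues, topology = c("circular", "linear"),
                            features = NULL) {
  topology <- match.arg(topology)
  residues <- normalize_residues(residues, what = sprintf("vector '%s'", name))
  if (is.null(features)) {
    features <- tibble::tibble(label = character(), start = integer(),
                               end = integer(), strand = character())
  }
  L <- nchar(residues)
  ok <- features$start >= 1L & features$end >= 1L & features$start <= L & features$end <= L
  if (!all(ok)) rlang::abort("feature intervals outside vector length")
  structure(
    list(name = name, residues = residues, topology = topology,
         features = tibble::as_tibble(features)),
    class = "vector_sequence"
  )
}

#' @export
print.vector_sequence <- function(x, ...) {
  cat(sprintf("<vector_sequence> %s: %d bp, %s, %d feature(s)\n",
              x$name, nchar(x$residues), x$topology, nrow(x$features)))
  invisible(x)
}

#' @export
length.vector_sequence <- function(x) nchar(x$residues)

#' Find restriction sites in a vector
#'
#' IUPAC-aware scan of the top strand for the recognition sequence and, for
#' non-palindromic enzymes, of the bottom strand (reported as the top-strand
#' start of the reverse-complement match). Circular molecules are scanned
#' across the origin. Positions are 1-based at the recognition start.
#'
#' @param vec A [vector_sequence()].
#' @param enzyme An enzyme (see [get_enzyme()]).
#' @return A tibble with columns `position`, `strand`.
#' @export
#' @examples
#' linker <- vector_sequence("linker", "GAATTCAAGCTTCTGCAG", "linear")
#' find_sites(linker, get_enzyme("EcoRI"))
find_sites <- function(vec, enzyme) {
  rec <- enzyme$recognition
  len <- nchar(rec)
  s <- vec$residues
  L <- nchar(s)
  scan_s <- if (vec$topology == "circular" && L >= len) {
    paste0(s, substr(s, 1, len - 1L))
  } else s
  scan_one <- function(pattern) {
    re <- paste0("(?=", iupac_to_regex(pattern), ")")
    m <- gregexpr(re, scan_s, perl = TRUE)[[1]]
    pos <- as.integer(m)
    pos[pos > 0]
  }
  plus <- scan_one(rec)
  rc <- revcomp(rec)
  minus <- if (identical(rc, rec)) integer(0) else scan_one(rc)
  out <- dplyr::bind_rows(
    tibble::tibble(position = plus, strand = "+"),
    tibble::tibble(position = minus, strand = "-")
  )
  out <- out[out$position <= L, , drop = FALSE]
  dplyr::arrange(out, .data$position, .data$strand)
}

# ---- digestion / ligation engine -------------------------------------------
#
# A digestion fragment is represented in top-strand orientation as:
#   seq   full top-strand span, INCLUDING any single-stranded overhang
#         regions at both ends
#   left/right end descriptors: list(type = "5p" | "3p" | "blunt",
#         strand = "top" | "bottom" | NA, ohang = overhang sequence written
#         in top-strand orientation)
# Two ends ligate iff both are blunt, or they share the overhang type, sit
# on opposite strands, and carry the same top-orientation overhang sequence.

frag_end <- function(type, strand = NA_character_, ohang = "") {
  list(type = type, strand = strand, ohang = ohang)
}

new_fragment <- function(seq, left, right) {
  list(seq = seq, left = left, right = right)
}

ends_compatible <- function(right, left) {
  if (right$type == "blunt" && left$type == "blunt") return(TRUE)
  right$type == left$type &&
    !is.na(right$strand) && !is.na(left$strand) &&
    right$strand != left$strand &&
    right$ohang == left$ohang
}

flip_end <- function(end) {
  if (end$type == "blunt") return(end)
  frag_end(end$type,
           strand = if (end$strand == "top") "bottom" else "top",
           ohang = revcomp(end$ohang))
}

flip_fragment <- function(f) {
  new_fragment(revcomp(f$seq), flip_end(f$right), flip_end(f$left))
}

# Double-stranded base count of a fragment (top span minus the two
# single-stranded overhang regions counted once each side).
fragment_base_count <- function(f) {
  # total nucleotides over both strands:
  # top strand length + bottom strand length
  top_len <- nchar(f$seq)
  left_ss <- nchar(f$left$ohang)
  right_ss <- nchar(f$right$ohang)
  bottom_len <- top_len -
    (if (!is.na(f$left$strand) && f$left$strand == "top") left_ss else 0L) -
    (if (!is.na(f$right$strand) && f$right$strand == "top") right_ss else 0L)
  top_only <- top_len -
    (if (!is.na(f$left$strand) && f$left$strand == "bottom") left_ss else 0L) -
    (if (!is.na(f$right$strand) && f$right$strand == "bottom") right_ss else 0L)
  top_only + bottom_len
}

# Cut coordinates of one site: positions X such that the strand is cut
# between X and X+1 (top-strand coordinates).
site_cuts <- function(position, strand, enzyme) {
  len <- nchar(enzyme$recognition)
  if (strand == "+") {
    list(top = position + enzyme$cut_top - 1L,
         bottom = position + enzyme$cut_bottom - 1L)
  } else {
    list(top = position + len - enzyme$cut_bottom - 1L,
         bottom = position + len - enzyme$cut_top - 1L)
  }
}

# Digest a vector with one or more enzymes; returns a list of fragments.
# Cuts whose coordinates fall outside a linear molecule are an error
# (type IIS site too close to an end). Circular molecules wrap.
digest <- function(vec, enzymes) {
  if (inherits(enzymes, "list") && !is.null(enzymes$name)) enzymes <- list(enzymes)
  s <- vec$residues
  L <- nchar(s)
  cuts <- list()
  for (enz in enzymes) {
    sites <- find_sites(vec, enz)
    for (i in seq_len(nrow(sites))) {
      cc <- site_cuts(sites$position[i], sites$strand[i], enz)
      cuts[[length(cuts) + 1L]] <- c(top = cc$top, bottom = cc$bottom)
    }
  }
  if (length(cuts) == 0) return(list(vector_as_fragment(vec)))
  cm <- do.call(rbind, cuts)
  if (vec$topology == "circular") {
    cm <- cm %% L
    cm[cm == 0L] <- L
    # order around the circle by top-cut coordinate
    cm <- cm[order(cm[, "top"]), , drop = FALSE]
    n <- nrow(cm)
    frags <- vector("list", n)
    dbl <- paste0(s, s)
    for (i in seq_len(n)) {
      a <- cm[i, ]
      b <- if (i < n) cm[i + 1L, ] else cm[1L, ] + L
      frags[[i]] <- make_cut_fragment(dbl, a, b)
    }
    frags
  } else {
    if (any(cm < 0L | cm > L)) {
      rlang::abort("cut position outside linear molecule")
    }
    cm <- cm[order(cm[, "top"]), , drop = FALSE]
    n <- nrow(cm)
    frags <- vector("list", n + 1L)
    left_bound <- c(top = 0L, bottom = 0L)
    for (i in seq_len(n)) {
      frags[[i]] <- make_cut_fragment(
        s, left_bound, cm[i, ],
        left_blunt = i == 1L
      )
      left_bound <- cm[i, ]
    }
    frags[[n + 1L]] <- make_cut_fragment(
      s, left_bound, c(top = L, bottom = L),
      right_blunt = TRUE
    )
    if (n >= 1L) frags[[1L]]$left <- frag_end("blunt")
    frags[[n + 1L]]$right <- frag_end("blunt")
    frags
  }
}

vector_as_fragment <- function(vec) {
  if (vec$topology == "circular") {
    rlang::abort("uncut circular molecule has no fragment representation")
  }
  new_fragment(vec$residues, frag_end("blunt"), frag_end("blunt"))
}

# Fragment between cut `a` (left) and cut `b` (right); cuts are (top, bottom)
# coordinate pairs meaning "cut after this top-strand position".
make_cut_fragment <- function(s, a, b, left_blunt = FALSE, right_blunt = FALSE) {
  span_start <- min(a) + 1L
  span_end <- max(b)
  seq <- substr(s, span_start, span_end)
  left <- if (left_blunt || a["top"] == a["bottom"]) {
    frag_end("blunt")
  } else if (a["top"] < a["bottom"]) {
    # top strand extends further left: 5' overhang on top
    frag_end("5p", "top", substr(s, a["top"] + 1L, a["bottom"]))
  } else {
    # bottom strand extends further left: its 3' end overhangs
    frag_end("3p", "bottom", substr(s, a["bottom"] + 1L, a["top"]))
  }
  right <- if (right_blunt || b["top"] == b["bottom"]) {
    frag_end("blunt")
  } else if (b["bottom"] > b["top"]) {
    # bottom strand extends further right: its 5' end overhangs
    frag_end("5p", "bottom", substr(s, b["top"] + 1L, b["bottom"]))
  } else {
    frag_end("3p", "top", substr(s, b["bottom"] + 1L, b["top"]))
  }
  new_fragment(seq, left, right)
}

# Join fragment B onto the right end of fragment A (ends must be compatible).
join_fragments <- function(a, b) {
  olen <- nchar(a$right$ohang)
  new_fragment(
    paste0(a$seq, substr(b$seq, olen + 1L, nchar(b$seq))),
    a$left, b$right
  )
}

# Assemble a set of fragments into a single circular molecule by overhang
# matching. Fragments may flip; assembly must use every fragment exactly
# once and be unambiguous at every join.
ligate_circular <- function(fragments, name = "assembly") {
  if (length(fragments) == 0) rlang::abort("cannot circularize: no fragments")
  cur <- fragments[[1]]
  used <- c(TRUE, rep(FALSE, length(fragments) - 1L))
  while (any(!used)) {
    options <- list()
    for (i in which(!used)) {
      f <- fragments[[i]]
      if (ends_compatible(cur$right, f$left)) {
        options[[length(options) + 1L]] <- list(i = i, frag = f)
      }
      ff <- flip_fragment(f)
      if (ends_compatible(cur$right, ff$left)) {
        options[[length(options) + 1L]] <- list(i = i, frag = ff)
      }
    }
    if (length(options) == 0) {
      rlang::abort("overhang mismatch: no fragment extends the assembly")
    }
    distinct <- unique(purrr::map_chr(options, function(o) {
      paste(o$frag$seq, o$frag$left$ohang, o$frag$right$ohang)
    }))
    if (length(distinct) > 1) {
      rlang::abort("ambiguous assembly: multiple fragments share a compatible overhang")
    }
    pick <- options[[1]]
    cur <- join_fragments(cur, pick$frag)
    used[pick$i] <- TRUE
  }
  if (!ends_compatible(cur$right, cur$left)) {
    rlang::abort("overhang mismatch: assembly cannot circularize")
  }
  olen <- nchar(cur$right$ohang)
  seq <- substr(cur$seq, 1L, nchar(cur$seq) - olen)
  # drop the left overhang region duplicated at the seam for 3' left overhangs
  vector_sequence(name, seq, "circular")
}

# ---- cloning operations -----------------------------------------------------

#' Derive a BioBrick-compatible backbone from an L4440-style vector
#'
#' Deletes the inclusive coordinate range carrying the bidirectional T7
#' promoters and inserts a short EcoRI-HindIII-PstI linker at the deletion
#' point, reproducing the published backbone surgery (2790 bp in, 2585 bp
#' out with the default 223-bp deletion and 18-nt linker). Features
#' overlapping the deleted range are dropped with a warning; features
#' downstream are shifted.
#'
#' @param l4440 A circular [vector_sequence()].
#' @param delete_start,delete_end 1-based inclusive deletion range.
#' @param linker Replacement sequence inserted at the deletion point.
#' @return A new `vector_sequence`.
#' @export
derive_biobrick_backbone <- function(l4440, delete_start = 1982L,
                                     delete_end = 2204L,
                                     linker = "GAATTCAAGCTTCTGCAG") {
  L <- nchar(l4440$residues)
  delete_start <- as.integer(delete_start); delete_end <- as.integer(delete_end)
  if (!(delete_start >= 1L && delete_start <= delete_end && delete_end <= L)) {
    rlang::abort("deletion range out of bounds")
  }
  s <- l4440$residues
  new_seq <- paste0(substr(s, 1L, delete_start - 1L), linker,
                    substr(s, delete_end + 1L, L))
  shift <- nchar(linker) - (delete_end - delete_start + 1L)
  ft <- l4440$features
  if (nrow(ft) > 0) {
    overlaps <- ft$start <= delete_end & ft$end >= delete_start
    if (any(overlaps)) {
      rlang::warn(sprintf("dropping %d feature(s) overlapping the deleted range: %s",
                          sum(overlaps), paste(ft$label[overlaps], collapse = ", ")))
    }
    ft <- ft[!overlaps, , drop = FALSE]
    after <- ft$start > delete_end
    ft$start[after] <- ft$start[after] + shift
    ft$end[after] <- ft$end[after] + shift
  }
  vector_sequence(paste0(l4440$name, "-BioBrick"), new_seq, l4440$topology, ft)
}

#' Insert an EcoRI/PstI-flanked payload into a BioBrick backbone
#'
#' Simulates the double digest of backbone (one EcoRI and one PstI site
#' required) and payload (flanked by EcoRI and PstI, no internal sites of
#' either), drops the backbone fragment between the two sites, and ligates
#' the payload core in the EcoRI→PstI orientation forced by the two
#' distinct sticky ends.
#'
#' @param backbone A circular [vector_sequence()] with exactly one EcoRI and
#'   one PstI site.
#' @param payload A linear [vector_sequence()] flanked by EcoRI and PstI.
#' @param registry Enzyme registry.
#' @return The circular product `vector_sequence`.
#' @export
assemble_biobrick_insert <- function(backbone, payload,
                                     registry = load_enzyme_registry()) {
  eco <- get_enzyme("EcoRI", registry)
  pst <- get_enzyme("PstI", registry)
  for (enz in list(eco, pst)) {
    nb <- nrow(find_sites(backbone, enz))
    if (nb != 1L) {
      rlang::abort(sprintf("backbone must contain exactly one %s site (found %d)",
                           enz$name, nb))
    }
    np <- nrow(find_sites(payload, enz))
    if (np == 0L) {
      rlang::abort(sprintf("payload is not flanked by an %s site", enz$name))
    }
    if (np > 1L) {
      rlang::abort(sprintf("payload contains an internal %s site", enz$name))
    }
  }
  bfrags <- digest(backbone, list(eco, pst))
  # keep the larger backbone fragment (carries replication origin etc.);
  # the smaller piece between the two sites is the dropout
  sizes <- purrr::map_int(bfrags, ~nchar(.x$seq))
  keep <- bfrags[[which.max(sizes)]]
  pfrags <- digest(payload, list(eco, pst))
  cut_ends <- purrr::map_lgl(pfrags, ~.x$left$type != "blunt" && .x$right$type != "blunt")
  if (sum(cut_ends) != 1L) {
    rlang::abort("payload does not release a unique EcoRI/PstI core fragment")
  }
  core <- pfrags[[which(cut_ends)]]
  ligate_circular(list(keep, core), name = paste0(backbone$name, "-insert"))
}

#' Design an annealed oligo duplex for a type IIS spacer slot
#'
#' Builds the two oligos that, once annealed, insert a 20-nt protospacer
#' into a golden-gate slot: the top oligo is the slot's top 5' overhang
#' followed by the protospacer; the bottom oligo is the slot's bottom 5'
#' overhang followed by the protospacer's reverse complement.
#'
#' @param protospacer 20-nt spacer sequence.
#' @param slot A list with `overhang_top` and `overhang_bottom` (both 4-nt,
#'   5'→3' on their own strands).
#' @return An object of class `oligo_duplex` (`top`, `bottom`,
#'   `overhang_top`, `overhang_bottom`).
#' @export
design_spacer_oligos <- function(protospacer, slot) {
  check_protospacer(protospacer, "protospacer")
  if (nchar(slot$overhang_top) != 4L || nchar(slot$overhang_bottom) != 4L) {
    rlang::abort("slot overhangs must be 4 nt")
  }
  structure(
    list(
      top = paste0(slot$overhang_top, protospacer),
      bottom = paste0(slot$overhang_bottom, revcomp(protospacer)),
      overhang_top = slot$overhang_top,
      overhang_bottom = slot$overhang_bottom
    ),
    class = "oligo_duplex"
  )
}

#' @export
print.oligo_duplex <- function(x, ...) {
  cat(sprintf("<oligo_duplex> top 5'-%s-3' / bottom 5'-%s-3'\n", x$top, x$bottom))
  invisible(x)
}

# Annealed-duplex fragment in top-strand orientation: the bottom oligo's 5'
# overhang sits at the RIGHT end of the duplex.
duplex_as_fragment <- function(dx) {
  core <- substr(dx$top, nchar(dx$overhang_top) + 1L, nchar(dx$top))
  new_fragment(
    paste0(dx$overhang_top, core, revcomp(dx$overhang_bottom)),
    frag_end("5p", "top", dx$overhang_top),
    frag_end("5p", "bottom", revcomp(dx$overhang_bottom))
  )
}

#' Simulate golden-gate insertion of spacer duplexes
#'
#' Digests the vector with the given type IIS enzyme, discards every
#' fragment still carrying a recognition site (the slot dropouts), and
#' reassembles the remaining backbone fragments together with the supplied
#' annealed duplexes by unique overhang matching. The product is circular
#' and free of residual sites of the enzyme; mismatched or ambiguous
#' overhangs abort the assembly.
#'
#' @param vec A circular [vector_sequence()] with type IIS slots.
#' @param duplexes A list of [design_spacer_oligos()] duplexes.
#' @param enzyme A type IIS enzyme (see [get_enzyme()]).
#' @return The circular product `vector_sequence`.
#' @export
simulate_golden_gate <- function(vec, duplexes, enzyme) {
  if (inherits(duplexes, "oligo_duplex")) duplexes <- list(duplexes)
  if (length(duplexes) == 0) {
    rlang::abort("no duplexes supplied: a slot-bearing vector cannot circularize")
  }
  ohs <- unlist(purrr::map(duplexes, ~c(.x$overhang_top, revcomp(.x$overhang_bottom))))
  if (anyDuplicated(ohs)) {
    rlang::abort("ambiguous assembly: two duplexes share an overhang")
  }
  frags <- digest(vec, enzyme)
  rec_re <- iupac_to_regex(enzyme$recognition)
  rc_re <- iupac_to_regex(revcomp(enzyme$recognition))
  has_site <- purrr::map_lgl(frags, function(f) {
    grepl(rec_re, f$seq) || grepl(rc_re, f$seq)
  })
  backbone <- frags[!has_site]
  if (length(backbone) == 0) {
    rlang::abort(sprintf("vector has no %s-free backbone fragment", enzyme$name))
  }
  pieces <- c(backbone, purrr::map(duplexes, duplex_as_fragment))
  product <- ligate_circular(pieces, name = paste0(vec$name, "-spacer"))
  residual <- nrow(find_sites(product, enzyme))
  if (residual > 0) {
    rlang::abort(sprintf("assembly left %d residual %s site(s)", residual, enzyme$name))
  }
  product
}

#' Validate a payload against BioBrick part rules
#'
#' Reports every internal occurrence of the BioBrick-forbidden restriction
#' sites (EcoRI, XbaI, SpeI, PstI by default) and checks the flanking
#' prefix/suffix convention: an EcoRI site opening the payload and a PstI
#' site closing it. Those two flank occurrences are not violations.
#'
#' @param payload DNA string (the part, including its flanking sites).
#' @param forbidden Names of forbidden enzymes.
#' @param registry Enzyme registry.
#' @return A list with `pass` (logical), `prefix_found`, `suffix_found`, and
#'   `violations` (tibble `enzyme`, `position`).
#' @export
validate_biobrick <- function(payload,
                              forbidden = c("EcoRI", "XbaI", "SpeI", "PstI"),
                              registry = load_enzyme_registry()) {
  payload <- normalize_residues(payload, "payload")
  vec <- vector_sequence("payload", payload, "linear")
  L <- nchar(payload)
  viol <- list()
  prefix_found <- FALSE
  suffix_found <- FALSE
  for (name in forbidden) {
    enz <- get_enzyme(name, registry)
    sites <- find_sites(vec, enz)
    for (p in sites$position) {
      if (name == "EcoRI" && p == 1L) {
        prefix_found <- TRUE
      } else if (name == "PstI" && p == L - nchar(enz$recognition) + 1L) {
        suffix_found <- TRUE
      } else {
        viol[[length(viol) + 1L]] <- tibble::tibble(enzyme = name, position = p)
      }
    }
  }
  violations <- if (length(viol) > 0) dplyr::bind_rows(viol) else {
    tibble::tibble(enzyme = character(), position = integer())
  }
  list(
    pass = nrow(violations) == 0,
    prefix_found = prefix_found,
    suffix_found = suffix_found,
    violations = dplyr::arrange(violations, .data$position)
  )
}

#' Write a vector as a minimal GenBank-style flat file
#'
#' Emits LOCUS / FEATURES / ORIGIN blocks sufficient for inspection in
#' standard viewers; not a full-fidelity GenBank writer.
#'
#' @param vec A [vector_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(vec, path) {
  L <- nchar(vec$residues)
  lines <- c(sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN",
                     substr(vec$name, 1, 17), L, vec$topology),
             "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(vec$features))) {
    f <- vec$features[i, ]
    loc <- if (f$strand == "-") sprintf("complement(%d..%d)", f$start, f$end)
           else sprintf("%d..%d", f$start, f$end)
    lines <- c(lines,
               sprintf("     misc_feature    %s", loc),
               sprintf("                     /label=\"%s\"", f$label))
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(vec$residues)
  for (start in seq(1L, L, by = 60L)) {
    chunk <- substr(s, start, min(L, start + 59L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10), pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    lines <- c(lines, sprintf("%9d %s", start, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
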