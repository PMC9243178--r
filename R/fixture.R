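#' Specify a synthetic genome fixture
#'
#' Describes a reproducible single-chromosome genome with `n_genes` TSSs on
#' alternating strands, engineered promoter PAM density, and optionally
#' planted off-target copies of designed guides. The fixture emulates the
#' inputs the design procedure consumes — a genome plus an experimentally
#' defined representative-TSS table — without requiring any download.
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp (default spaces genes 2 kb
#'   apart with 1 kb margins).
#' @param seed Integer RNG seed; the fixture is byte-identical under a
#'   fixed seed.
#' @param pam_density `"natural"` (background sequence as drawn),
#'   `"saturated"` (PAMs planted so candidate protospacers start every
#'   `pam_spacing` bp across the whole window, including candidates whose
#'   distal base sits exactly `far` bp and whose proximal base sits exactly
#'   `near` bp upstream of the TSS), or `"none"` (windows scrubbed of
#'   NGG/CCN).
#' @param planted_offtargets Optional tibble (`gene`, `mismatches`,
#'   `copies`): for each row, the first candidate guide of that gene (1-based
#'   index) is copied `copies` times with exactly `mismatches` substitutions
#'   and an NGG PAM into intergenic sequence.
#' @param gc_background Background GC fraction.
#' @param pam_spacing Candidate start spacing under `"saturated"` (bp).
#' @param params A [design_params()] object (window geometry).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 10L, chrom_length = NULL, seed = 1L,
                         pam_density = c("natural", "saturated", "none"),
                         planted_offtargets = NULL, gc_background = 0.5,
                         pam_spacing = 8L, params = design_params()) {
  pam_density <- match.arg(pam_density)
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) rlang::abort("n_genes must be >= 1")
  spacing <- 2000L
  margin <- 1000L
  if (is.null(chrom_length)) chrom_length <- n_genes * spacing + 2L * margin
  chrom_length <- as.integer(chrom_length)
  if (chrom_length < n_genes * spacing + 2L * margin) {
    rlang::abort("infeasible spec: windows would overlap chromosome ends")
  }
  structure(
    list(n_genes = n_genes, chrom_length = chrom_length, seed = as.integer(seed),
         pam_density = pam_density, planted_offtargets = planted_offtargets,
         gc_background = gc_background, pam_spacing = as.integer(pam_spacing),
         params = params, spacing = spacing, margin = margin),
    class = "fixture_spec"
  )
}

#' Generate a synthetic genome fixture
#'
#' Materialises a [fixture_spec()]: a genome tibble, a representative-TSS
#' table (every gene has an adult TSS; every third gene also carries an
#' embryonic TSS 100 bp away, exercising the stage-preference rule), and a
#' truth manifest recording everything that was planted.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `genome` (tibble), `tss` (tibble), `truth` (list with
#'   `tss_positions`, `pam_starts` per gene, `planted_offtargets` tibble).
#' @export
generate_fixture <- function(spec) {
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
  set.seed(spec$seed)
  p <- spec$params
  gc <- spec$gc_background
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(probs), spec$chrom_length, replace = TRUE, prob = probs)

  tss_pos <- spec$margin + spec$spacing * (seq_len(spec$n_genes) - 1L) +
    spec$spacing %/% 2L
  strands <- rep(c("+", "-"), length.out = spec$n_genes)

  pam_starts <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    tss <- tss_pos[g]
    strand <- strands[g]
    if (spec$pam_density == "saturated") {
      # Candidate starts every pam_spacing bp from the window's distal edge,
      # plus the start whose protospacer ends exactly `near` bp upstream.
      min_off <- p$near + p$guide_len - 1L  # proximal-most distal-base offset
      start_offs <- unique(c(seq(p$far, min_off, by = -spec$pam_spacing), min_off))
      # `start_offs` are upstream offsets of the protospacer's distal base
      if (strand == "+") {
        starts <- tss - start_offs                       # genomic protospacer starts
        gg <- c(starts + p$guide_len + 1L)               # PAM GG positions (N is free)
        for (x in gg) { bases[x] <- "G"; bases[x + 1L] <- "G" }
        pam_starts[[g]] <- starts
      } else {
        starts <- tss + start_offs - p$guide_len + 1L    # top-strand start of 20-mer
        cc <- starts - 3L                                # PAM CC positions on top strand
        for (x in cc) { bases[x] <- "C"; bases[x + 1L] <- "C" }
        pam_starts[[g]] <- starts
      }
    } else if (spec$pam_density == "none") {
      lo <- if (strand == "+") tss - p$far - 3L else tss + p$near - 3L
      hi <- if (strand == "+") tss - p$near + 3L else tss + p$far + 3L
      region <- lo:hi
      # remove every GG and CC dinucleotide so no NGG PAM survives on
      # either strand
      repeat {
        gg <- which(bases[region[-length(region)]] == bases[region[-1]] &
                      bases[region[-length(region)]] %in% c("G", "C"))
        if (length(gg) == 0) break
        bases[region[gg + 1L]] <- ifelse(bases[region[gg]] == "G", "A", "T")
      }
      pam_starts[[g]] <- integer(0)
    } else {
      pam_starts[[g]] <- integer(0)
    }
  }

  residues <- paste(bases, collapse = "")
  genome <- tibble::tibble(seq_id = "chrS", residues = residues,
                           length = nchar(residues))
  tss <- tibble::tibble(
    gene_id = sprintf("SYNGENE%04d", seq_len(spec$n_genes)),
    public_name = sprintf("syn-%d", seq_len(spec$n_genes)),
    chrom = "chrS",
    position = as.integer(tss_pos),
    strand = strands,
    stage = "adult"
  )
  embryonic <- tss[seq_len(spec$n_genes) %% 3L == 1L, ]
  if (nrow(embryonic) > 0) {
    embryonic$position <- embryonic$position +
      ifelse(embryonic$strand == "+", -100L, 100L)
    embryonic$stage <- "embryonic"
    tss <- dplyr::arrange(dplyr::bind_rows(tss, embryonic),
                          .data$gene_id, .data$stage)
  }

  planted <- tibble::tibble(
    gene = integer(), guide = character(), chrom = character(),
    start = integer(), strand = character(), mismatches = integer()
  )
  if (!is.null(spec$planted_offtargets) && nrow(spec$planted_offtargets) > 0) {
    insert_at <- spec$chrom_length - spec$margin %/% 2L
    for (i in seq_len(nrow(spec$planted_offtargets))) {
      row <- spec$planted_offtargets[i, ]
      gene_tss <- tss[tss$gene_id == sprintf("SYNGENE%04d", row$gene) &
                        tss$stage == "adult", ]
      win <- promoter_window(gene_tss, p, chrom_length = nchar(genome$residues))
      cands <- enumerate_candidates(win, genome, p)
      if (nrow(cands) == 0) rlang::abort("planted_offtargets: gene has no candidate guide")
      guide <- cands$protospacer[1]
      for (k in seq_len(row$copies)) {
        mutated <- strsplit(guide, "")[[1]]
        mut_pos <- round(seq(3, 18, length.out = row$mismatches)) + (k - 1L)
        for (mp in mut_pos) {
          mutated[mp] <- setdiff(c("A", "C", "G", "T"), mutated[mp])[1]
        }
        copy_seq <- paste0(paste(mutated, collapse = ""), "TGG")
        substr(residues, insert_at, insert_at + nchar(copy_seq) - 1L) <- copy_seq
        planted <- dplyr::bind_rows(planted, tibble::tibble(
          gene = row$gene, guide = guide, chrom = "chrS",
          start = as.integer(insert_at), strand = "+",
          mismatches = as.integer(row$mismatches)
        ))
        insert_at <- insert_at + 40L
      }
    }
    genome$residues <- residues
    genome$length <- nchar(residues)
  }

  list(
    genome = genome,
    tss = tss,
    truth = list(
      tss_positions = stats::setNames(as.integer(tss_pos), tss$gene_id[tss$stage == "adult"]),
      pam_starts = pam_starts,
      planted_offtargets = planted
    )
  )
}

#' Build a length-faithful synthetic L4440-style placeholder vector
#'
#' A 2790-bp circular molecule standing in for the real plasmid, whose
#' sequence is not bundled: the backbone is seeded random sequence scrubbed
#' of EcoRI/HindIII/PstI/XbaI/SpeI/BsaI/BbsI sites, and the region deleted
#' during BioBrick derivation (1982-2204 by default) is filled with a
#' repeated sentinel motif so tests can verify its complete removal. Only
#' the coordinate arithmetic of the real derivation is faithful; the
#' residues are synthetic.
#'
#' @param length Total length in bp.
#' @param delete_start,delete_end Sentinel-filled region.
#' @param seed RNG seed.
#' @return A circular [vector_sequence()].
#' @export
synthetic_l4440 <- function(length = 2790L, delete_start = 1982L,
                            delete_end = 2204L, seed = 42L) {
  s <- random_scrubbed_dna(length, seed)
  sentinel <- "ACTCATTCAGGTACAATCGA"  # motif absent after scrubbed-region surgery
  fill <- strrep(sentinel, ceiling((delete_end - delete_start + 1L) / nchar(sentinel)))
  substr(s, delete_start, delete_end) <- substr(fill, 1L, delete_end - delete_start + 1L)
  s <- scrub_sites(s)
  vector_sequence(
    "synthetic-L4440", s, "circular",
    features = tibble::tibble(
      label = "bidirectional-T7-placeholder",
      start = delete_start, end = delete_end, strand = "+"
    )
  )
}

#' Build a structurally faithful synthetic dual-slot sgRNA cassette
#'
#' A linear payload emulating the published dual sgRNA expression cassette's
#' architecture — EcoRI prefix, two promoter-labelled spacer slots each
#' flanked by inward-facing type IIS sites (BbsI and BsaI by default, so
#' each slot opens with its own enzyme), scaffold placeholders, PstI suffix
#' — with synthetic residues everywhere else. The slot overhang
#' specifications are attached as the `"slots"` attribute for
#' [design_spacer_oligos()].
#'
#' @param slot_enzymes Length-2 character vector naming the type IIS enzyme
#'   of each slot.
#' @param seed RNG seed for the synthetic filler.
#' @param registry Enzyme registry.
#' @return A linear [vector_sequence()] with attribute `slots` (list of two
#'   lists with `overhang_top`, `overhang_bottom`).
#' @export
synthetic_cassette <- function(slot_enzymes = c("BbsI", "BsaI"), seed = 7L,
                               registry = load_enzyme_registry()) {
  stopifnot(length(slot_enzymes) == 2L)
  # backbone overhangs (o_left, o_right), all distinct, none palindromic
  overhangs <- list(c("GTTT", "CGAA"), c("CACC", "TGGA"))
  # G-free filler: every registered recognition sequence contains a G, so
  # junctions between filler and the designed elements can never create an
  # unintended restriction site
  filler <- function(n, shift) {
    chars <- c("A", "C", "T")
    paste(chars[((seq_len(n) * (seed + shift)) %% 3L) + 1L], collapse = "")
  }
  slots <- list()
  mids <- character(2)
  for (i in 1:2) {
    enz <- get_enzyme(slot_enzymes[i], registry)
    o_left <- overhangs[[i]][1]
    o_right <- overhangs[[i]][2]
    mids[i] <- build_type2s_slot(enz, o_left, o_right, filler(20L, 10L + i))
    # overhang_bottom of the annealing duplex is the revcomp of the right
    # backbone overhang (5'->3' on the bottom strand)
    slots[[i]] <- list(overhang_top = o_left, overhang_bottom = revcomp(o_right))
  }
  seq <- paste0(
    "GAATTC", filler(30L, 1L),          # EcoRI prefix + T7 promoter placeholder
    mids[1],
    filler(40L, 2L),                     # scaffold placeholder
    filler(30L, 3L),                     # second T7 promoter placeholder
    mids[2],
    filler(40L, 4L),                     # scaffold placeholder
    "CTGCAG"                             # PstI suffix
  )
  vec <- vector_sequence("synthetic-dual-sgRNA-cassette", seq, "linear")
  attr(vec, "slots") <- slots
  vec
}

# Slot layout for an enzyme cutting downstream of its recognition with a 5'
# overhang: [left overhang][spacer][recognition, minus strand] dropout
# [recognition, plus strand][spacer][right overhang]; after digestion the
# recognition sites leave with the dropout and the flanks keep the two
# overhangs.
build_type2s_slot <- function(enzyme, o_left, o_right, dropout_fill) {
  len <- nchar(enzyme$recognition)
  gap <- enzyme$cut_top - len   # bases between recognition end and top cut
  stopifnot(gap >= 1L, nchar(o_left) == 4L, nchar(o_right) == 4L)
  spacer <- function(n, base = "A") strrep(base, n)
  paste0(
    o_left, spacer(gap), revcomp(enzyme$recognition),
    dropout_fill,
    enzyme$recognition, spacer(gap), o_right
  )
}

# Seeded random DNA free of the registry enzymes' recognition sites (both
# strands).
random_scrubbed_dna <- function(n, seed) {
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
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  scrub_sites(s)
}

scrub_sites <- function(s) {
  registry <- load_enzyme_registry()
  pats <- unique(c(registry$recognition, revcomp(registry$recognition)))
  repeat {
    found <- FALSE
    for (p in pats) {
      i <- regexpr(p, s, fixed = TRUE)
      if (i > 0) {
        # flip the middle base to break the site deterministically
        mid <- as.integer(i) + nchar(p) %/% 2L
        cur <- substr(s, mid, mid)
        substr(s, mid, mid) <- c(A = "C", C = "A", G = "T", T = "G")[cur]
        found <- TRUE
      }
    }
    if (!found) break
  }
  s
}
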