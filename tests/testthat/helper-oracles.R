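# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's vectorised scanning internals:
# everything here is a plain per-position loop over character vectors.

random_dna <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Naive double-strand candidate scan: for every start inside the window,
# check protospacer containment, PAM presence in the genome, and N overlap.
oracle_candidates <- function(window, chrom_seq, glen = 20L) {
  tss <- window$tss_position
  out <- list()
  L <- nchar(chrom_seq)
  for (s in window$start:(window$end - glen + 1L)) {
    proto <- substr(chrom_seq, s, s + glen - 1L)
    if (grepl("N", proto, fixed = TRUE)) next
    # plus strand
    if (s + glen + 2L <= L) {
      pam <- substr(chrom_seq, s + glen, s + glen + 2L)
      if (grepl("^[ACGT]GG$", pam)) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = s + glen - 1L, strand = "+",
          protospacer = proto, pam = pam
        )
      }
    }
    # minus strand
    if (s - 3L >= 1L) {
      pam <- oracle_revcomp(substr(chrom_seq, s - 3L, s - 1L))
      if (grepl("^[ACGT]GG$", pam)) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = s + glen - 1L, strand = "-",
          protospacer = oracle_revcomp(proto), pam = pam
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      protospacer = character(), pam = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Naive genome-wide near-match scan with NGG PAM, both strands. A plain
# per-position loop; the only concession to speed is splitting each string
# into a character vector once.
oracle_near_matches <- function(guide, chrom_seq, max_mm) {
  L <- nchar(chrom_seq)
  glen <- nchar(guide)
  sv <- strsplit(chrom_seq, "")[[1]]
  gv <- strsplit(guide, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  gv_rc <- rev(unname(comp[gv]))
  out <- list()
  for (s in seq_len(L - glen + 1L)) {
    word <- sv[s:(s + glen - 1L)]
    if (s + glen + 2L <= L &&
        sv[s + glen + 1L] == "G" && sv[s + glen + 2L] == "G" &&
        sv[s + glen] %in% c("A", "C", "G", "T")) {
      mm <- sum(word != gv)
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "+", mismatches = mm)
      }
    }
    if (s - 3L >= 1L &&
        sv[s - 3L] == "C" && sv[s - 2L] == "C" &&
        sv[s - 1L] %in% c("A", "C", "G", "T")) {
      mm <- sum(word != gv_rc)
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "-", mismatches = mm)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character(), mismatches = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

# PAM-agnostic variant used for scramble-control vetting.
oracle_near_matches_pamfree <- function(guide, chrom_seq, max_mm) {
  L <- nchar(chrom_seq)
  glen <- nchar(guide)
  out <- list()
  for (s in seq_len(L - glen + 1L)) {
    word <- substr(chrom_seq, s, s + glen - 1L)
    if (oracle_hamming(guide, word) <= max_mm) {
      out[[length(out) + 1L]] <- data.frame(start = s, strand = "+")
    }
    if (oracle_hamming(guide, oracle_revcomp(word)) <= max_mm) {
      out[[length(out) + 1L]] <- data.frame(start = s, strand = "-")
    }
  }
  if (length(out) == 0) return(data.frame(start = integer(), strand = character()))
  do.call(rbind, out)
}

# Plain-arithmetic genome table constructor for in-memory sequences.
genome_tbl <- function(..., ids = NULL) {
  seqs <- c(...)
  if (is.null(ids)) ids <- paste0("chr", seq_along(seqs))
  tibble::tibble(seq_id = ids, residues = seqs, length = nchar(seqs))
}

# Manual promoter-window row (bypasses promoter_window for unit scans).
window_row <- function(chrom, start, end, strand = "+", tss = 10000L,
                       gene_id = "g1") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 tss_position = as.integer(tss), clamped = FALSE)
}

tss_row <- function(gene_id = "g1", chrom = "chr1", position = 1000L,
                    strand = "+", stage = "adult", public_name = gene_id) {
  tibble::tibble(gene_id = gene_id, public_name = public_name, chrom = chrom,
                 position = as.integer(position), strand = strand, stage = stage)
}
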