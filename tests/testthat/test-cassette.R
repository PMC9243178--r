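filler <- function(n) substr(strrep("ACT", ceiling(n / 3) + 1), 1, n)

test_that("the EcoRI-HindIII-PstI linker parses with sites at 1, 7, 13", {
  linker <- vector_sequence("linker", "GAATTCAAGCTTCTGCAG", "linear")
  expect_equal(nchar(linker$residues), 18L)
  expect_equal(find_sites(linker, get_enzyme("EcoRI"))$position, 1L)
  expect_equal(find_sites(linker, get_enzyme("HindIII"))$position, 7L)
  expect_equal(find_sites(linker, get_enzyme("PstI"))$position, 13L)
})

test_that("non-palindromic recognition is found on the minus strand", {
  v <- vector_sequence("v", paste0(filler(20), "GAGACC", filler(20)), "linear")
  sites <- find_sites(v, get_enzyme("BsaI"))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "-")
  expect_equal(sites$position, 21L)
})

test_that("circular scanning finds sites split across the origin", {
  v <- vector_sequence("wrap", paste0("TTC", filler(60), "GAA"), "circular")
  sites <- find_sites(v, get_enzyme("EcoRI"))
  expect_equal(sites$position, 64L)
  # the same molecule treated as linear has no site
  vl <- vector_sequence("wrap", v$residues, "linear")
  expect_equal(nrow(find_sites(vl, get_enzyme("EcoRI"))), 0L)
})

test_that("find_sites equals a naive scan oracle on random sequences", {
  for (seed in 1:40) {
    s <- random_dna(400, 300 + seed)
    topo <- if (seed %% 2 == 0) "circular" else "linear"
    v <- vector_sequence("r", s, topo)
    for (enz_name in c("EcoRI", "BsaI", "BbsI")) {
      enz <- get_enzyme(enz_name)
      got <- find_sites(v, enz)
      scan <- if (topo == "circular") paste0(s, substr(s, 1, 5)) else s
      fwd <- which(vapply(seq_len(nchar(s)), function(i)
        substr(scan, i, i + 5) == enz$recognition, TRUE))
      rc <- oracle_revcomp(enz$recognition)
      rev <- if (rc == enz$recognition) integer(0) else
        which(vapply(seq_len(nchar(s)), function(i)
          substr(scan, i, i + 5) == rc, TRUE))
      want <- c(if (length(fwd) > 0) paste(fwd, "+"),
                if (length(rev) > 0) paste(rev, "-"))
      expect_setequal(paste(got$position, got$strand),
                      if (is.null(want)) character(0) else want)
    }
  }
})

test_that("BioBrick backbone derivation reproduces the published arithmetic", {
  l4440 <- synthetic_l4440()
  expect_equal(nchar(l4440$residues), 2790L)
  expect_warning(bb <- derive_biobrick_backbone(l4440), "dropping 1 feature")
  expect_equal(nchar(bb$residues), 2585L)
  # the 18-nt linker sits exactly at the deletion point
  expect_equal(substr(bb$residues, 1982, 1999), "GAATTCAAGCTTCTGCAG")
  # the sentinel motif filling the deleted range is gone without trace
  expect_false(grepl("ACTCATTCAGGTACAATCGA", bb$residues, fixed = TRUE))
  expect_true(grepl("ACTCATTCAGGTACAATCGA", l4440$residues, fixed = TRUE))
  # the derived backbone has unique EcoRI/HindIII/PstI sites (from the linker)
  for (e in c("EcoRI", "HindIII", "PstI")) {
    expect_equal(nrow(find_sites(bb, get_enzyme(e))), 1L)
  }
  expect_error(derive_biobrick_backbone(l4440, 100, 5000), "out of bounds")
})

test_that("deletion length identity holds for arbitrary ranges and linkers", {
  for (seed in 1:30) {
    L <- withr::with_seed(seed, sample(200:600, 1))
    v <- vector_sequence("r", random_dna(L, 500 + seed), "circular")
    del <- withr::with_seed(seed + 50, sort(sample(L, 2)))
    linker <- random_dna(withr::with_seed(seed + 99, sample(5:30, 1)), seed)
    out <- derive_biobrick_backbone(v, del[1], del[2], linker)
    expect_equal(nchar(out$residues),
                 L - (del[2] - del[1] + 1L) + nchar(linker))
  }
})

test_that("EcoRI/PstI insertion matches an independent cut-and-paste prediction", {
  backbone_seq <- paste0(filler(9), "GAATTC", filler(24), "CTGCAG", filler(55))
  backbone <- vector_sequence("toy", backbone_seq, "circular")
  payload_seq <- paste0(filler(5), "GAATTC", filler(18), "CTGCAG", filler(5))
  payload <- vector_sequence("ins", payload_seq, "linear")
  product <- assemble_biobrick_insert(backbone, payload)
  # manual digest arithmetic: EcoRI top cut after 10, PstI top cut after 44
  # on the backbone (dropout arc 34); payload top cuts after 6 and 34
  # (core 28): product = 100 - 34 + 28
  expect_equal(nchar(product$residues), 94L)
  expect_equal(product$topology, "circular")
  # the payload core appears exactly once (scan across the origin)
  core <- substr(payload_seq, 7, 34)
  doubled <- paste0(product$residues, product$residues)
  starts <- gregexpr(core, doubled, fixed = TRUE)[[1]]
  starts <- starts[starts > 0 & starts <= nchar(product$residues)]
  expect_length(starts, 1L)
  # re-digesting the product releases a fragment carrying the core
  frags <- promoterguide:::digest(product, list(get_enzyme("EcoRI"), get_enzyme("PstI")))
  expect_equal(length(frags), 2L)
  expect_true(any(vapply(frags, function(f) grepl(filler(18), f$seq, fixed = TRUE), TRUE)))
})

test_that("insertion refuses malformed substrates", {
  backbone <- vector_sequence("toy", paste0(filler(9), "GAATTC", filler(24),
                                            "CTGCAG", filler(55)), "circular")
  # internal PstI site in the payload
  bad <- vector_sequence("bad", paste0(filler(5), "GAATTC", filler(6), "CTGCAG",
                                       filler(6), "CTGCAG", filler(5)), "linear")
  expect_error(assemble_biobrick_insert(backbone, bad), "internal PstI")
  # payload missing the EcoRI flank
  no_eco <- vector_sequence("ne", paste0(filler(12), "CTGCAG", filler(5)), "linear")
  expect_error(assemble_biobrick_insert(backbone, no_eco), "not flanked by an EcoRI")
  # backbone with two EcoRI sites
  bb2 <- vector_sequence("b2", paste0(filler(9), "GAATTC", filler(10), "GAATTC",
                                      filler(14), "CTGCAG", filler(45)), "circular")
  good <- vector_sequence("ok", paste0(filler(5), "GAATTC", filler(18), "CTGCAG",
                                       filler(5)), "linear")
  expect_error(assemble_biobrick_insert(bb2, good), "exactly one EcoRI")
})

test_that("digest/ligate cycles conserve total base count", {
  v <- vector_sequence("toy", paste0(filler(9), "GAATTC", filler(24),
                                     "CTGCAG", filler(55)), "circular")
  frags <- promoterguide:::digest(v, list(get_enzyme("EcoRI"), get_enzyme("PstI")))
  total_nt <- sum(vapply(frags, promoterguide:::fragment_base_count, 1L))
  expect_equal(total_nt, 2L * nchar(v$residues))
  relig <- promoterguide:::ligate_circular(frags)
  expect_equal(nchar(relig$residues), nchar(v$residues))
})

test_that("spacer oligo duplexes anneal with the stated overhangs", {
  proto <- "GATTACAGATTACAGATTAC"
  slot <- list(overhang_top = "GTTT", overhang_bottom = "TTCG")
  dx <- design_spacer_oligos(proto, slot)
  expect_equal(dx$top, paste0("GTTT", proto))
  expect_equal(dx$bottom, paste0("TTCG", oracle_revcomp(proto)))
  # annealed cores are reverse complements
  expect_equal(substr(dx$bottom, 5, 24), oracle_revcomp(substr(dx$top, 5, 24)))
  expect_error(design_spacer_oligos("ACGT", slot), "20 nt")
})

make_double_slot_vector <- function() {
  bbs <- get_enzyme("BbsI")
  slot1 <- promoterguide:::build_type2s_slot(bbs, "GTTT", "CGAA", filler(21))
  slot2 <- promoterguide:::build_type2s_slot(bbs, "CACC", "TGGA", filler(24))
  vector_sequence("2slot", paste0(filler(40), slot1, filler(30), slot2, filler(35)),
                  "circular")
}

test_that("golden-gate assembly fills both slots and removes every site", {
  vec <- make_double_slot_vector()
  expect_equal(nrow(find_sites(vec, get_enzyme("BbsI"))), 4L)
  p1 <- "GATTACAGATTACAGATTAC"
  p2 <- "TGCATGCAAGGTACGTTAGA"
  d1 <- design_spacer_oligos(p1, list(overhang_top = "GTTT", overhang_bottom = "TTCG"))
  d2 <- design_spacer_oligos(p2, list(overhang_top = "CACC", overhang_bottom = "TCCA"))
  out <- simulate_golden_gate(vec, list(d1, d2), get_enzyme("BbsI"))
  expect_equal(nrow(find_sites(out, get_enzyme("BbsI"))), 0L)
  for (p in c(p1, p2)) {
    expect_equal(stringr::str_count(out$residues, stringr::fixed(p)), 1L)
  }
  # insertion is directional: each spacer sits between its slot's flanks
  expect_true(grepl(paste0("GTTT", p1), out$residues, fixed = TRUE))
  expect_true(grepl(paste0("CACC", p2), out$residues, fixed = TRUE))
  # duplex input order does not matter
  out2 <- simulate_golden_gate(vec, list(d2, d1), get_enzyme("BbsI"))
  expect_identical(out2$residues, out$residues)
})

test_that("golden-gate refuses scrambled overhangs and empty duplex sets", {
  vec <- make_double_slot_vector()
  p1 <- "GATTACAGATTACAGATTAC"
  wrong <- design_spacer_oligos(p1, list(overhang_top = "AGGT", overhang_bottom = "ACCA"))
  expect_error(simulate_golden_gate(vec, list(wrong), get_enzyme("BbsI")),
               "mismatch|circularize")
  expect_error(simulate_golden_gate(vec, list(), get_enzyme("BbsI")),
               "cannot circularize")
  # two duplexes sharing an overhang are ambiguous
  dup <- design_spacer_oligos("TGCATGCAAGGTACGTTAGA",
                              list(overhang_top = "GTTT", overhang_bottom = "TTCG"))
  d1 <- design_spacer_oligos(p1, list(overhang_top = "GTTT", overhang_bottom = "TTCG"))
  expect_error(simulate_golden_gate(vec, list(d1, dup), get_enzyme("BbsI")),
               "ambiguous")
})

test_that("the full vector build chains backbone, cassette, and both slots", {
  bb <- suppressWarnings(derive_biobrick_backbone(synthetic_l4440()))
  cassette <- synthetic_cassette()
  slots <- attr(cassette, "slots")
  sg_vec <- assemble_biobrick_insert(bb, cassette)
  expect_equal(sg_vec$topology, "circular")
  p1 <- "GATTACAGATTACAGATTAC"
  p2 <- "TGCATGCAAGGTACGTTAGA"
  step1 <- simulate_golden_gate(sg_vec, list(design_spacer_oligos(p1, slots[[1]])),
                                get_enzyme("BbsI"))
  step2 <- simulate_golden_gate(step1, list(design_spacer_oligos(p2, slots[[2]])),
                                get_enzyme("BsaI"))
  expect_equal(stringr::str_count(step2$residues, stringr::fixed(p1)), 1L)
  expect_equal(stringr::str_count(step2$residues, stringr::fixed(p2)), 1L)
  expect_equal(nrow(find_sites(step2, get_enzyme("BbsI"))), 0L)
  expect_equal(nrow(find_sites(step2, get_enzyme("BsaI"))), 0L)
})

test_that("BioBrick validation reports internal forbidden sites with positions", {
  clean <- paste0("GAATTC", filler(30), "CTGCAG")
  rep1 <- validate_biobrick(clean)
  expect_true(rep1$pass)
  expect_true(rep1$prefix_found)
  expect_true(rep1$suffix_found)

  dirty <- paste0("GAATTC", filler(10), "GAATTC", filler(9), "TCTAGA",
                  filler(10), "CTGCAG")
  rep2 <- validate_biobrick(dirty)
  expect_false(rep2$pass)
  expect_equal(nrow(rep2$violations), 2L)
  expect_setequal(rep2$violations$enzyme, c("EcoRI", "XbaI"))
  expect_equal(sort(rep2$violations$position), c(17L, 32L))
})

test_that("vectors export to a readable GenBank-style flat file", {
  v <- vector_sequence("demo", random_dna(150, 9), "circular",
                       features = tibble::tibble(label = "slot", start = 10L,
                                                 end = 40L, strand = "-"))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(v, gb)
  txt <- readLines(gb)
  expect_match(txt[1], "LOCUS\\s+demo\\s+150 bp")
  expect_true(any(grepl("complement\\(10..40\\)", txt)))
  expect_identical(txt[length(txt)], "//")
})
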