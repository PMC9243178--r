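test_that("candidate enumeration matches the worked single-candidate case", {
  # 27-nt sequence, window = first 24 positions: one plus-strand candidate
  # whose AGG PAM sits just outside the window; no reverse-strand CCN hit
  g <- genome_tbl("ACGTACGTACGTACGTACGTAGGAAAA", ids = "w")
  win <- window_row("w", 1, 24, "+", tss = 2000)
  cand <- enumerate_candidates(win, g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$protospacer, "ACGTACGTACGTACGTACGT")
  expect_equal(cand$pam, "AGG")
  expect_equal(cand$strand, "+")
  expect_equal(c(cand$start, cand$end), c(1L, 20L))
})

test_that("poly-A windows yield nothing; poly-G windows only plus-strand runs", {
  win <- window_row("w", 1, 351, "+", tss = 2000)
  expect_equal(nrow(enumerate_candidates(window_row("a", 1, 351), genome_tbl(strrep("A", 351), ids = "a"))), 0L)
  cand <- enumerate_candidates(win, genome_tbl(strrep("G", 351), ids = "w"))
  expect_equal(sum(cand$strand == "+"), 329L)
  expect_equal(sum(cand$strand == "-"), 0L)
  expect_equal(range(cand$start), c(1L, 329L))
})

test_that("candidates never overlap N and report coordinates self-consistently", {
  s <- random_dna(600, 11)
  substr(s, 300, 302) <- "NNN"
  g <- genome_tbl(s, ids = "c")
  win <- window_row("c", 100, 450, "+", tss = 500)
  cand <- enumerate_candidates(win, g)
  expect_true(nrow(cand) > 0)
  for (i in seq_len(nrow(cand))) {
    word <- substr(s, cand$start[i], cand$end[i])
    looked_up <- if (cand$strand[i] == "+") word else oracle_revcomp(word)
    expect_identical(cand$protospacer[i], looked_up)
    expect_false(grepl("N", cand$protospacer[i]))
  }
})

test_that("enumeration equals the brute-force double-strand oracle on random windows", {
  p <- design_params()
  for (seed in 1:200) {
    L <- 120L
    s <- random_dna(L, seed, gc = if (seed %% 3 == 0) 0.7 else 0.5)
    if (seed %% 10 == 0) substr(s, 50, 52) <- "NNN"
    g <- genome_tbl(s, ids = "r")
    ws <- withr::with_seed(seed + 1000, sample(1:40, 1))
    we <- ws + withr::with_seed(seed + 2000, sample(25:70, 1))
    win <- window_row("r", ws, min(we, L), "+", tss = 4000)
    got <- enumerate_candidates(win, g, p)
    want <- oracle_candidates(win, s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$protospacer, want$protospacer)
      expect_equal(got$pam, want$pam)
    }
  }
})

test_that("on-target scoring reproduces closed-form logistic anchors", {
  null_model <- on_target_model()
  expect_equal(on_target_score(strrep("A", 30), null_model), 50)
  # one unit weight on G at protospacer position 20 (30-mer position 24)
  m <- on_target_model(tibble::tibble(position = 24L, token = "G", weight = 1))
  ctx <- paste0(strrep("A", 23), "G", strrep("A", 6))
  expect_equal(on_target_score(ctx, m), 100 * plogis(1), tolerance = 1e-12)
  expect_equal(on_target_score(ctx, m), 73.10585786300048, tolerance = 1e-9)
  # context without the G keeps the null score
  expect_equal(on_target_score(strrep("A", 30), m), 50)
})

test_that("the shipped weight table reproduces its independently computed value", {
  # frozen from a straight-line evaluation of inst/extdata/on_target_weights.tsv
  ctx <- "ACGTGATTACAGATTACAGATTACTGGCGA"
  expect_equal(on_target_score(ctx), 37.989356765690985, tolerance = 1e-9)
})

test_that("on-target score is monotone in any matched feature weight", {
  ctx <- "ACGTGATTACAGATTACAGATTACTGGCGA"
  for (w in c(-1, -0.2, 0.3, 2)) {
    m <- on_target_model(tibble::tibble(position = 5L, token = "G", weight = w))
    m2 <- on_target_model(tibble::tibble(position = 5L, token = "G", weight = w + 0.5))
    expect_true(on_target_score(ctx, m2) > on_target_score(ctx, m))
  }
  expect_error(on_target_score("ACGT"), "30 nt")
  expect_error(on_target_score(paste0(strrep("A", 29), "N")), "A/C/G/T")
})

test_that("strict filtering keeps only guides above both thresholds, ranked", {
  cand <- tibble::tibble(
    gene_id = "g", protospacer = c("AAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCC",
                                   "GGGGGGGGGGGGGGGGGGGG"),
    tss_offset_near = c(60L, 70L, 80L),
    on_score = c(80, 40, 60), spec_score = c(90, 95, 30)
  )
  kept <- filter_and_rank(cand)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$on_score, 80)

  # ranking: on-target first, specificity breaks ties, then proximity
  cand2 <- tibble::tibble(
    gene_id = "g",
    protospacer = c("TTTTTTTTTTTTTTTTTTTT", "AAAAAAAAAAAAAAAAAAAA",
                    "CCCCCCCCCCCCCCCCCCCC", "GGGGGGGGGGGGGGGGGGGG"),
    tss_offset_near = c(60L, 70L, 90L, 80L),
    on_score = c(60, 91, 91, 91), spec_score = c(91, 60, 99, 99)
  )
  ranked <- filter_and_rank(cand2, mode = "permissive")
  expect_equal(ranked$on_score[1], 91)
  expect_equal(ranked$spec_score[1:2], c(99, 99))
  expect_equal(ranked$tss_offset_near[1:2], c(80L, 90L))
  expect_equal(ranked$on_score[4], 60)
  expect_true(all(ranked$pass))

  expect_error(filter_and_rank(dplyr::select(cand, -on_score)), "scored")
})

test_that("guide labels are two-digit, rounded half-up, clamped", {
  p20 <- "GATTACAGATTACAGATTAC"
  expect_equal(format_guide_label(87.4, p20), paste0("87_", p20))
  expect_equal(format_guide_label(87.5, p20), paste0("88_", p20))
  expect_equal(format_guide_label(5.0, p20), paste0("05_", p20))
  expect_equal(format_guide_label(99.8, p20), paste0("99_", p20))
})

test_that("scramble controls have exact GC, avoid the genome, and are reproducible", {
  g <- genome_tbl(random_dna(50000, 1), ids = "chrS")
  scr <- generate_scramble(5, seed = 1, genome = g)
  expect_equal(nrow(scr), 5L)
  expect_true(all(nchar(scr$sequence) == 20L))
  expect_true(all(vapply(scr$sequence, function(x)
    sum(strsplit(x, "")[[1]] %in% c("G", "C")), 1L) == 10L))
  # deterministic under (n, seed, genome)
  expect_identical(generate_scramble(5, seed = 1, genome = g), scr)
  expect_false(identical(generate_scramble(5, seed = 2, genome = g)$sequence,
                         scr$sequence))
})

test_that("a scramble colliding with a planted genomic 20-mer is resampled", {
  tiny <- genome_tbl(strrep("AT", 200), ids = "t")
  first <- generate_scramble(1, seed = 3, genome = tiny)$sequence
  # plant that exact draw in the genome; same seed must now skip it
  planted <- genome_tbl(paste0(strrep("AT", 200), first, strrep("TA", 200)), ids = "t")
  scr <- generate_scramble(3, seed = 3, genome = planted)
  expect_false(first %in% scr$sequence)
  rej <- attr(scr, "rejections")
  expect_true(first %in% rej$sequence)
  # emitted sequences genuinely have no near-match (brute-force check)
  for (x in scr$sequence) {
    expect_equal(nrow(oracle_near_matches_pamfree(x, planted$residues, 4L)), 0L)
  }
})
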