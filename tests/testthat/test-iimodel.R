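test_that("PFM counts tally columns and strand-doubling symmetrizes", {
  for (seed in 1:10) {
    n <- 5L + seed
    L <- 4L + (seed %% 5L)
    seqs <- random_dna(n, L, seed = seed)
    pfm <- build_pfm(seqs)
    expect_identical(as.integer(colSums(pfm$counts)), rep(n, L))
    expect_equal(colSums(pfm$freq), rep(1, L), tolerance = 1e-12)
  }
  pfm2 <- build_pfm(c("AAAA", "AAAA"))
  expect_equal(unname(pfm2$freq["A", ]), rep(1, 4))

  both <- build_pfm(random_dna(10, 6, seed = 2), both_strands = TRUE)
  expect_identical(both$n, 20L)
  # both-strand counting makes the matrix reverse-complement symmetric
  mirror <- both$counts[4:1, 6:1]
  expect_identical(unname(both$counts), unname(mirror))

  expect_error(build_pfm(c("ACGT", "ACG")), "alignment")
  expect_error(build_pfm(c("ACGT", "ACNT")), "alphabet")
  expect_error(build_pfm("ACGT"), "at least 2")
})

test_that("small-sample correction: exact values, monotone decay", {
  expect_identical(small_sample_correction(1), 2)
  # two draws: P(same base) = 1/4 -> H = 0, else H = 1; e(2) = 2 - 3/4
  expect_equal(small_sample_correction(2), 1.25, tolerance = 1e-12)
  # frozen value from an independent plain-loop composition enumeration
  expect_equal(small_sample_correction(37), 0.0599485341937953,
               tolerance = 1e-9)
  en <- vapply(1:100, small_sample_correction, 0)
  expect_true(all(diff(en) < 0))
  expect_true(all(en > 0))
  e_big <- withr::with_seed(1,
    small_sample_correction(1e6, method = "monte_carlo", nsim = 2000L))
  expect_lt(abs(e_big), 1e-5)
  expect_error(small_sample_correction(0), "n must be")
})

test_that("mean training Ri equals Rsequence exactly (algebraic identity)", {
  for (seed in c(3, 11)) {
    seqs <- random_dna(25, 10, seed = seed)
    m <- build_model(build_pfm(seqs))
    expect_equal(mean(ri_score(m, seqs)), m$rsequence, tolerance = 1e-12)
    # row permutation leaves Rsequence unchanged
    m2 <- build_model(build_pfm(rev(seqs)))
    expect_identical(m2$rsequence, m$rsequence)
  }
  # uniform columns: H(l) = 2, so Rsequence = -L * e(n) exactly
  mu <- build_model(build_pfm(c("AAAA", "CCCC", "GGGG", "TTTT")))
  expect_equal(mu$rsequence, -4 * mu$e_n, tolerance = 1e-12)
  # large uniform random alignment scores about zero bits
  big <- build_model(build_pfm(random_dna(500, 8, seed = 5)))
  expect_lt(abs(big$rsequence), 0.5)
})

test_that("consensus dominates every sequence of the model width", {
  m <- toy_model(n = 12, L = 5, seed = 9, zero_count_policy = "pseudocount")
  cons <- consensus_sequence(m)
  grids <- do.call(expand.grid, rep(list(BASES), 5))
  all5 <- do.call(paste0, grids)
  scores <- ri_score(m, all5)
  expect_equal(max(scores), m$consensus_ri, tolerance = 1e-12)
  expect_identical(all5[which.max(scores)], as.character(cons))
  expect_equal(m$consensus_ri, unname(ri_score(m, as.character(cons))),
               tolerance = 1e-12)
  # model of two copies of one sequence reproduces it
  m2 <- build_model(build_pfm(c("ACGTT", "ACGTT")))
  expect_identical(as.character(consensus_sequence(m2)), "ACGTT")
  expect_length(attr(consensus_sequence(m2), "ties"), 0L)
})

test_that("zero-count policies: -Inf default, finite pseudocount fallback", {
  seqs <- c("AAAA", "AACA", "AAGA")
  m_inf <- build_model(build_pfm(seqs))
  expect_identical(unname(ri_score(m_inf, "TAAA")), -Inf)
  m_pse <- build_model(build_pfm(seqs), zero_count_policy = "pseudocount")
  expect_true(is.finite(ri_score(m_pse, "TAAA")))
  expect_error(ri_score(m_inf, "AAAAA"), "length")
  expect_error(ri_score(m_inf, "AANA"), "alphabet")
  expect_length(ri_score(m_inf, character(0)), 0L)
})

test_that("model serialization round-trips bit-exactly", {
  m <- build_arg_model()
  path <- withr::local_tempfile(fileext = ".mat")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$riw, m$riw)
  expect_identical(m2$rsequence, m$rsequence)
  expect_identical(m2$e_n, m$e_n)
  expect_identical(m2$pfm$counts, m$pfm$counts)
  probe <- random_dna(20, 20, seed = 13)
  expect_identical(ri_score(m2, probe), ri_score(m, probe))
})

test_that("logo stacks are clamped frequencies times information", {
  m <- build_model(build_pfm(c("AAAA", "CCCC", "GGGG", "TTTT")))
  ld <- logo_data(m)
  expect_true(all(ld$stack_height == 0))  # uniform columns clamp to 0
  m2 <- build_model(build_pfm(rep("ACGT", 50)))
  ld2 <- logo_data(m2)
  expect_true(all(abs(ld2$stack_height - (2 - m2$e_n)) < 1e-12))
  # stack total equals Rsequence when no column is negative
  m3 <- build_arg_model()
  ld3 <- logo_data(m3)
  stacks <- unique(ld3[, c("position", "stack_height")])$stack_height
  expect_equal(sum(stacks), sum(pmax(0, 2 - m3$H - m3$e_n)),
               tolerance = 1e-12)
})
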