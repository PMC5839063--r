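test_that("noiseless ZOOPS recovery hits the exact planted offsets", {
  # one exact consensus box per sequence in distinct random flanks: the box
  # is the only shared signal, so recovery must be perfect
  m <- build_arg_model()
  cons <- as.character(consensus_sequence(m))
  offs <- c(5L, 11L, 17L, 23L, 29L, 35L, 8L, 14L, 20L, 26L)
  seqs <- vapply(1:10, function(i) {
    fl <- random_dna(1, 60, seed = 30 + i)
    paste0(substr(fl, 1, offs[i] - 1L), cons, substr(fl, offs[i] + 20L, 60))
  }, "")
  names(seqs) <- paste0("p", 1:10)
  mo <- em_discover(seqs, width_min = 20, width_max = 20,
                    mode = "zoops", palindrome = TRUE, seed = 1)
  expect_identical(nrow(mo$site_calls), 10L)
  expect_identical(mo$site_calls$offset,
                   offs[match(mo$site_calls$seq_id, names(seqs))])
  expect_identical(hamming_rc(mo$consensus, cons), 0L)
})

test_that("palindrome constraint is a symmetrization fixed point", {
  m <- build_arg_model()
  pr <- generate_probe_sets(m, n_pos = 12, n_neg = 8, probe_len = 60,
                            seed = 41)
  mo <- em_discover(pr$positives, pr$negatives, width_min = 20,
                    width_max = 20, mode = "zoops", palindrome = TRUE,
                    seed = 41)
  mirror <- mo$freq[4:1, 20:1]
  expect_lt(max(abs(mo$freq - mirror)), 1e-9)
  expect_true(all(abs(colSums(mo$freq) - 1) < 1e-12))
})

test_that("EM objective is non-decreasing and runs are bit-reproducible", {
  m <- build_arg_model()
  pr <- generate_probe_sets(m, n_pos = 15, n_neg = 10, probe_len = 80,
                            seed = 5)
  mo1 <- em_discover(pr$positives, pr$negatives, width_min = 20,
                     width_max = 20, mode = "zoops", seed = 5)
  expect_gte(mo1$min_trace_delta, -1e-8)
  expect_true(all(diff(mo1$trace) > -1e-8))
  mo2 <- em_discover(pr$positives, pr$negatives, width_min = 20,
                     width_max = 20, mode = "zoops", seed = 5)
  expect_identical(mo1$freq, mo2$freq)
  expect_identical(mo1$site_calls, mo2$site_calls)
  expect_identical(mo1$trace, mo2$trace)
})

test_that("called windows align and feed model building", {
  toy <- list(width = 4L,
              site_calls = data.frame(seq_id = c("a", "b"),
                                      offset = c(1L, 1L),
                                      strand = c("+", "-"),
                                      posterior = 1))
  class(toy) <- "arg_motif"
  al <- site_calls_to_alignment(toy, c(a = "ACGTAA", b = "ACGTAA"))
  expect_identical(unname(al), c("ACGT", reverse_complement("ACGT")))

  bad <- toy
  bad$site_calls$offset[1] <- 5L
  expect_error(site_calls_to_alignment(bad, c(a = "ACGTAA", b = "ACGTAA")),
               "geometry")

  # pipeline: discover -> align -> rebuild recovers the planted conservation
  m <- build_arg_model()
  pr <- generate_probe_sets(m, n_pos = 20, n_neg = 12, probe_len = 80,
                            seed = 7)
  mo <- em_discover(pr$positives, pr$negatives, width_min = 20,
                    width_max = 20, mode = "zoops", seed = 7)
  rebuilt <- build_model(build_pfm(site_calls_to_alignment(mo, pr$positives),
                                   both_strands = TRUE))
  planted <- build_model(build_pfm(pr$truth$box1_seq, both_strands = TRUE))
  expect_lt(abs(rebuilt$rsequence - planted$rsequence), 0.5)
})

test_that("ANR mode calls multiple non-overlapping sites per sequence", {
  m <- build_arg_model()
  cons <- as.character(consensus_sequence(m))
  probes <- vapply(1:12, function(i) {
    paste0(random_dna(1, 10, seed = 50 + i), cons,
           random_dna(1, 5, seed = 70 + i), cons,
           random_dna(1, 10, seed = 90 + i))
  }, "")
  names(probes) <- paste0("p", 1:12)
  mo <- em_discover(probes, width_min = 20, width_max = 20, mode = "anr",
                    palindrome = TRUE, seed = 2, anr_max_sites = 2)
  calls_per_seq <- table(mo$site_calls$seq_id)
  expect_gte(mean(calls_per_seq), 1.5)
  expect_true(all(calls_per_seq <= 2L))
  # non-overlap within a sequence
  for (id in names(calls_per_seq)) {
    off <- sort(mo$site_calls$offset[mo$site_calls$seq_id == id])
    if (length(off) > 1) expect_true(all(diff(off) >= 20L))
  }
  # every call sits on a planted box (a palindromic target admits a small
  # mirror-register ambiguity, so allow a 2-nt phase)
  expect_true(all(pmin(abs(mo$site_calls$offset - 11L),
                       abs(mo$site_calls$offset - 36L)) <= 2L))
  expect_true(all(mo$site_calls$posterior > 0.9))
  # the recovered matrix honors the palindrome constraint
  expect_lt(max(abs(mo$freq - mo$freq[4:1, 20:1])), 1e-9)
})

test_that("discriminative fit separates planted from pure background", {
  m <- build_arg_model()
  pr <- generate_probe_sets(m, n_pos = 15, n_neg = 10, probe_len = 80,
                            seed = 13)
  planted <- em_discover(pr$positives, pr$negatives, width_min = 20,
                         width_max = 20, mode = "zoops", seed = 13)
  null_pos <- stats::setNames(
    vapply(1:15, function(i)
      generate_background(80, 0.72, seed = 200 + i)[[1]], ""),
    paste0("n", 1:15))
  null_fit <- em_discover(null_pos, pr$negatives, width_min = 20,
                          width_max = 20, mode = "zoops", seed = 13)
  expect_gt(planted$llr, null_fit$llr)
})
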