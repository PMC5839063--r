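test_that("DP score distribution equals exhaustive enumeration", {
  for (L in 3:5) {
    m <- toy_model(n = 10, L = L, seed = L,
                   zero_count_policy = "pseudocount")
    for (q in list(rep(0.25, 4), c(0.14, 0.36, 0.36, 0.14))) {
      for (type in c("log_odds", "ri")) {
        d <- score_distribution(m, background = q, type = type)
        expect_equal(sum(d$pmf), 1, tolerance = 1e-9)
        bf <- brute_force_tail(d, L)
        dp <- argboxr:::tail_at_bin(d, bf$k)
        expect_equal(dp, bf$tail, tolerance = 1e-12)
      }
    }
  }
})

test_that("p-value edges: support bounds and the top-score mass", {
  m <- toy_model(n = 10, L = 5, seed = 2,
                 zero_count_policy = "pseudocount")
  d <- score_distribution(m, background = rep(0.25, 4), type = "ri")
  expect_identical(pvalue(d, d$support[1] - 1), 1)
  expect_identical(pvalue(d, d$support[2] + 1), 0)
  # under a uniform background the consensus is the unique top scorer, so
  # the tail at the maximum equals its own probability 0.25^L
  if (length(attr(consensus_sequence(m), "ties")) == 0L) {
    expect_equal(pvalue(d, d$support[2]), 0.25^5, tolerance = 1e-12)
  }
  expect_error(score_distribution(m, granularity = 0), "granularity")
  expect_error(score_distribution(m, granularity = 100), "resolution")
})

test_that("scanning recovers the consensus and rejects trivial genomes", {
  m <- build_arg_model()
  cons <- as.character(consensus_sequence(m))
  h <- scan_sequence(c(g = cons), m)
  expect_identical(nrow(h), 1L)
  expect_identical(c(h$left, h$right), c(1L, 20L))
  expect_identical(h$strand, "+")
  expect_equal(h$ri, m$consensus_ri, tolerance = 1e-9)

  expect_identical(nrow(scan_sequence(c(a = strrep("A", 100)), m)), 0L)

  # windows containing N are skipped and counted
  gn <- paste0(substr(cons, 1, 10), "N", substr(cons, 12, 20))
  hn <- scan_sequence(c(g = gn), m)
  expect_identical(nrow(hn), 0L)
  expect_identical(attr(hn, "n_skipped"), 1L)
})

test_that("strand symmetry: scanning a sequence and its reverse complement", {
  # asymmetric toy model so both strands are genuinely scanned
  m <- toy_model(n = 10, L = 4, seed = 6,
                 zero_count_policy = "pseudocount")
  g <- random_dna(1, 300, seed = 8)
  h_fwd <- scan_sequence(c(g = g), m, p_max = 0.05, ri_min = -100,
                         background = "uniform")
  h_rev <- scan_sequence(c(g = reverse_complement(g)), m, p_max = 0.05,
                         ri_min = -100, background = "uniform")
  expect_identical(nrow(h_fwd), nrow(h_rev))
  # reflected coordinates with swapped strands
  glen <- nchar(g)
  reflected <- data.frame(left = glen - h_rev$right + 1L,
                          right = glen - h_rev$left + 1L,
                          strand = ifelse(h_rev$strand == "+", "-", "+"),
                          ri = h_rev$ri)
  reflected <- reflected[order(reflected$left, reflected$strand), ]
  fwd <- h_fwd[order(h_fwd$left, h_fwd$strand),
               c("left", "right", "strand", "ri")]
  expect_equal(unname(as.matrix(reflected[, 1:2])),
               unname(as.matrix(fwd[, 1:2])))
  expect_identical(reflected$strand, fwd$strand)
  expect_equal(sort(reflected$ri), sort(fwd$ri), tolerance = 1e-9)
})

test_that("tightening either filter never adds hits", {
  m <- build_arg_model()
  pl <- plant_sites(generate_background(5e4, 0.72, seed = 21), m,
                    n_sites = 5, ri_target = 14, seed = 22)
  loose <- scan_sequence(pl$sequence, m, p_max = 1e-3, ri_min = 5)
  for (flt in list(c(1e-5, 5), c(1e-3, 12), c(1e-5, 12))) {
    tight <- scan_sequence(pl$sequence, m, p_max = flt[1], ri_min = flt[2])
    expect_lte(nrow(tight), nrow(loose))
    key <- function(h) paste(h$left, h$strand)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("background hit counts are calibrated to the exact p-value level", {
  # with the Ri filter disabled, the expected hit count is windows times
  # the exact tail mass at the p-value cut
  m <- build_arg_model()
  total <- 0
  expected <- 0
  for (seed in 1:5) {
    g <- generate_background(2e5, 0.72, seed = 100 + seed)
    h <- scan_sequence(g, m, p_max = 1e-5, ri_min = -Inf)
    total <- total + nrow(h)
    x <- match(strsplit(g[[1]], "", fixed = TRUE)[[1]], BASES)
    q <- tabulate(x, 4) / length(x)
    q <- (q + q[4:1]) / 2
    d <- score_distribution(m, background = q)
    level <- max(d$tail[d$tail < 1e-5])
    expected <- expected + (nchar(g[[1]]) - 19) * level
  }
  # Poisson fluctuation bound (4 sd)
  expect_lt(abs(total - expected), 4 * sqrt(expected) + 1)
})

test_that("site assembly pairs adjacent hits greedily", {
  mk <- function(lefts, ri = 12) {
    n <- length(lefts)
    data.frame(chrom = rep("c", n), left = lefts, right = lefts + 19L,
               strand = rep("+", n), ri = rep(ri, length.out = n),
               p_value = rep(1e-6, n))
  }
  a <- assemble_sites(mk(c(1L, 21L)))
  expect_identical(a$kind, "tandem_contiguous")
  expect_identical(a$gap_nt, 0L)
  expect_equal(a$combined_ri, 24)

  b <- assemble_sites(mk(c(1L, 22L)))
  expect_identical(b$kind, "tandem_gap1")

  # three mutually adjacent: leftmost pair plus a single
  tri <- assemble_sites(mk(c(1L, 21L, 41L)))
  expect_identical(tri$kind, c("tandem_contiguous", "single"))
  expect_identical(sum(tri$n_boxes), 3L)

  far <- assemble_sites(mk(c(1L, 100L)))
  expect_identical(far$kind, c("single", "single"))
  expect_identical(nrow(assemble_sites(mk(integer(0)))), 0L)
})

test_that("gene association follows the downstream-gene rule", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = "c", strand = "+",
                      start_codon = c(151L, 400L, 900L))
  site <- data.frame(site_id = "s1", chrom = "c", left = 101L, right = 120L)
  asc <- associate_genes(site, genes)
  expect_identical(asc$gene_id, c("g1", "g2"))
  expect_identical(asc$distance[1], 30L)  # 30 nt upstream of the start
  expect_identical(asc$rank, 1:2)

  # site overlapping a start codon reports that gene with negative distance
  ov <- data.frame(site_id = "s2", chrom = "c", left = 140L, right = 159L)
  asc2 <- associate_genes(ov, genes)
  expect_identical(asc2$gene_id[1], "g1")
  expect_lt(asc2$distance[1], 0L)

  # minus-strand gene: distance measured in its reading direction
  gm <- data.frame(gene_id = "gm", chrom = "c", strand = "-",
                   start_codon = 70L)
  asc3 <- associate_genes(site, gm)
  expect_identical(asc3$distance, 30L)

  # site downstream of every gene on the contig
  past <- data.frame(site_id = "s3", chrom = "c", left = 950L, right = 969L)
  expect_warning(out <- associate_genes(past, genes[1:2, ]), "no site")
  expect_identical(nrow(out), 0L)
})

test_that("distance convention: abutting is zero, overlap negative", {
  expect_identical(distance_to_start(101L, 120L, 151L, "+"), 30L)
  expect_identical(distance_to_start(101L, 120L, 121L, "+"), 0L)
  expect_identical(distance_to_start(101L, 120L, 108L, "+"), -13L)
  expect_identical(distance_to_start(101L, 120L, 100L, "-"), 0L)
  expect_identical(distance_to_start(101L, 120L, 114L, "-"), -14L)
})
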