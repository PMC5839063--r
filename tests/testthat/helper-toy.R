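# shared test utilities: deterministic toy data builders

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, len, seed = 1L, prob = rep(0.25, 4L)) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
  }, ""))
}

# small model from a random alignment
toy_model <- function(n = 12L, L = 5L, seed = 1L, ...) {
  build_model(build_pfm(random_dna(n, L, seed)), ...)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Hamming distance up to reverse complementation (palindromic motifs are
# recovered in an arbitrary orientation)
hamming_rc <- function(a, b) {
  min(hamming(a, b), hamming(reverse_complement(a), b))
}

# brute-force binned score tail over all 4^L sequences, the independent
# oracle for the DP distribution
brute_force_tail <- function(dist, L) {
  grids <- do.call(expand.grid, rep(list(1:4), L))
  ks <- Reduce(`+`, lapply(seq_len(L), function(l) {
    dist$kmat[cbind(grids[[l]], l)]
  }))
  pr <- Reduce(`*`, lapply(seq_len(L), function(l) {
    dist$background[grids[[l]]]
  }))
  uk <- sort(unique(ks))
  list(k = uk,
       tail = vapply(uk, function(k) sum(pr[ks >= k]), 0))
}
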