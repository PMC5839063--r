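#' Position frequency matrix of an aligned binding-site collection
#'
#' Tallies per-column base counts of equal-length, gap-free DNA sequences.
#' For palindromic (dyad-symmetric) sites the alignment can be counted on
#' both strands: each sequence then contributes itself and its reverse
#' complement, which symmetrizes the matrix and doubles the row count.
#'
#' @param seqs Character vector of equal-length ACGT sequences (at least 2).
#' @param L Expected width; taken from the sequences when `NULL`.
#' @param both_strands Count each sequence on both strands (default `FALSE`).
#' @return An object of class `arg_pfm`: list with `counts` (4 x L integer
#'   matrix, rows A,C,G,T), `freq`, `n` (rows counted), `L`, `both_strands`.
#' @export
build_pfm <- function(seqs, L = NULL, both_strands = FALSE) {
  if (length(seqs) < 2L) {
    stop("need at least 2 sequences to build a frequency matrix",
         call. = FALSE)
  }
  widths <- nchar(seqs)
  if (is.null(L)) L <- widths[1L]
  if (any(widths != L)) {
    bad <- which(widths != L)[1L]
    stop("alignment error: sequence ", bad, " has length ", widths[bad],
         ", expected ", L, call. = FALSE)
  }
  if (both_strands) seqs <- c(seqs, reverse_complement(seqs))
  M <- seq_matrix(seqs)
  if (anyNA(M)) {
    stop("alphabet error: sequences must contain only A, C, G, T",
         call. = FALSE)
  }
  counts <- vapply(seq_len(L), function(l) {
    tabulate(M[, l], nbins = 4L)
  }, integer(4L))
  dimnames(counts) <- list(DNA_BASES, NULL)
  n <- length(seqs)
  structure(list(counts = counts, freq = counts / n, n = n, L = as.integer(L),
                 both_strands = both_strands),
            class = "arg_pfm")
}

# integer-coded sequence matrix (rows = sequences), NA for non-ACGT
seq_matrix <- function(seqs) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  t(vapply(chars, function(ch) match(ch, DNA_BASES), integer(nchar(seqs[1L]))))
}

# x*log2(x) with 0*log(0) = 0
xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Small-sample entropy correction e(n)
#'
#' Expected upward bias, in bits, of the plug-in entropy of a 4-letter
#' alphabet estimated from `n` independent draws of the uniform base
#' distribution: `e(n) = 2 - E[H_obs]`. Subtracting it makes random
#' alignments score about zero bits per position. The default method
#' enumerates all compositions of `n` into 4 parts with multinomial weights
#' (exact and deterministic); `"monte_carlo"` estimates the same expectation
#' by simulation for very large `n`.
#'
#' @param n Number of aligned sequences (>= 1).
#' @param method `"exact"` (enumeration) or `"monte_carlo"`.
#' @param nsim Monte-Carlo replicates.
#' @return e(n) in bits.
#' @export
small_sample_correction <- function(n, method = c("exact", "monte_carlo"),
                                    nsim = 10000L) {
  method <- match.arg(method)
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(round(n))
  if (method == "monte_carlo") {
    counts <- stats::rmultinom(nsim, n, rep(0.25, 4L))
    H <- colSums(-xlog2x(counts / n))
    return(2 - mean(H))
  }
  key <- as.character(n)
  if (!is.null(the$e_cache[[key]])) return(the$e_cache[[key]])
  # enumerate compositions (a, b, c, n-a-b-c) vectorized over (a, b)
  lf <- lfactorial
  eh <- 0
  for (a in 0:n) {
    b <- 0:(n - a)
    # for each b, c runs 0..(n-a-b); build flat vectors
    reps <- n - a - b + 1L
    bb <- rep.int(b, reps)
    cc <- sequence(reps) - 1L
    dd <- n - a - bb - cc
    logp <- lf(n) - lf(a) - lf(bb) - lf(cc) - lf(dd) + n * log(0.25)
    H <- -(xlog2x(a / n) + xlog2x(bb / n) + xlog2x(cc / n) + xlog2x(dd / n))
    eh <- eh + sum(exp(logp) * H)
  }
  e <- 2 - eh
  if (is.null(the$e_cache)) the$e_cache <- list()
  the$e_cache[[key]] <- e
  e
}

#' Build an individual-information model from a frequency matrix
#'
#' Computes per-position observed entropies `H(l)`, the small-sample
#' correction `e(n)`, the weight matrix `Riw(b,l) = 2 + log2 f(b,l) - e(n)`,
#' and the model conservation `Rsequence = sum_l [2 - H(l) - e(n)]`. Under
#' the default `"minus_infinity"` zero-count policy, bases never observed at
#' a position score `-Inf`; the `"pseudocount"` policy instead smooths the
#' frequencies with `alpha` added to every count before taking logs
#' (`Rsequence` and `H` always use the raw frequencies).
#'
#' @param pfm An `arg_pfm` from [build_pfm()].
#' @param zero_count_policy `"minus_infinity"` or `"pseudocount"`.
#' @param alpha Pseudocount added to each cell count under the
#'   `"pseudocount"` policy (default 0.25, i.e. 0.25/n in frequency units).
#' @param e_method Passed to [small_sample_correction()].
#' @return An object of class `arg_iimodel`: list with `pfm`, `n`, `L`,
#'   `e_n`, `H` (bits per position), `riw` (4 x L weight matrix, bits),
#'   `rsequence` (bits), `consensus` (character string, attribute `ties`
#'   marks positions whose maximum frequency is shared), `consensus_ri`,
#'   `policy`, `alpha`.
#' @export
build_model <- function(pfm, zero_count_policy = c("minus_infinity",
                                                   "pseudocount"),
                        alpha = 0.25, e_method = "exact") {
  policy <- match.arg(zero_count_policy)
  stopifnot(inherits(pfm, "arg_pfm"))
  f <- pfm$freq
  H <- apply(f, 2L, function(p) -sum(xlog2x(p)))
  e_n <- small_sample_correction(pfm$n, method = e_method)
  if (policy == "minus_infinity") {
    riw <- 2 + log2(f) - e_n      # -Inf where f = 0
  } else {
    fs <- (pfm$counts + alpha) / (pfm$n + 4 * alpha)
    riw <- 2 + log2(fs) - e_n
  }
  rsequence <- sum(2 - H - e_n)
  cons_idx <- apply(f, 2L, which.max)
  ties <- vapply(seq_len(pfm$L),
                 function(l) sum(f[, l] == max(f[, l])) > 1L, logical(1L))
  consensus <- paste(DNA_BASES[cons_idx], collapse = "")
  attr(consensus, "ties") <- which(ties)
  model <- structure(list(pfm = pfm, n = pfm$n, L = pfm$L, e_n = e_n, H = H,
                          riw = riw, rsequence = rsequence,
                          consensus = consensus,
                          consensus_ri = sum(apply(riw, 2L, max)),
                          policy = policy, alpha = alpha),
                     class = "arg_iimodel")
  model
}

#' @export
print.arg_iimodel <- function(x, ...) {
  cat("Individual-information model\n")
  cat(sprintf("  width L       : %d nt\n", x$L))
  cat(sprintf("  sequences n   : %d%s\n", x$n,
              if (isTRUE(x$pfm$both_strands)) " (both strands counted)" else ""))
  cat(sprintf("  e(n)          : %.4f bits/position\n", x$e_n))
  cat(sprintf("  Rsequence     : %.2f bits\n", x$rsequence))
  cat(sprintf("  consensus     : %s (Ri = %.2f bits)\n",
              as.character(x$consensus), x$consensus_ri))
  invisible(x)
}

#' Individual information (Ri) of sequences under a model
#'
#' `Ri(s) = sum_l Riw(s_l, l)` in bits. Under the `minus_infinity` policy a
#' sequence using a never-observed base at some position scores `-Inf`.
#'
#' @param model An `arg_iimodel`.
#' @param seqs Character vector of sequences of the model width.
#' @return Named numeric vector of scores in bits.
#' @export
ri_score <- function(model, seqs) {
  stopifnot(inherits(model, "arg_iimodel"))
  if (length(seqs) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(nchar(seqs) != model$L)) {
    stop("scoring error: all sequences must have length ", model$L,
         call. = FALSE)
  }
  M <- seq_matrix(seqs)
  if (anyNA(M)) {
    stop("alphabet error: sequences must contain only A, C, G, T",
         call. = FALSE)
  }
  idx <- cbind(as.vector(t(M)), rep(seq_len(model$L), length(seqs)))
  scores <- rowSums(matrix(model$riw[idx], ncol = model$L, byrow = TRUE))
  stats::setNames(scores, names(seqs))
}

#' Consensus sequence of a model
#'
#' Per-position most frequent base; ties are broken by the fixed base order
#' A < C < G < T and flagged in the `ties` attribute (tied positions).
#'
#' @param model An `arg_iimodel`.
#' @return Character scalar with attribute `ties`.
#' @export
consensus_sequence <- function(model) {
  stopifnot(inherits(model, "arg_iimodel"))
  model$consensus
}

#' Sequence-logo table of a model
#'
#' Per-position letter stacks: stack height is the (zero-clamped)
#' information `max(0, 2 - H(l) - e(n))` in bits and letter heights
#' partition each stack proportionally to the base frequencies.
#'
#' @param model An `arg_iimodel`.
#' @return Data frame with `position`, `base`, `freq`, `stack_height`,
#'   `letter_height`.
#' @export
logo_data <- function(model) {
  stopifnot(inherits(model, "arg_iimodel"))
  stack <- pmax(0, 2 - model$H - model$e_n)
  f <- model$pfm$freq
  data.frame(
    position = rep(seq_len(model$L), each = 4L),
    base = rep(DNA_BASES, model$L),
    freq = as.vector(f),
    stack_height = rep(stack, each = 4L),
    letter_height = as.vector(f) * rep(stack, each = 4L),
    stringsAsFactors = FALSE
  )
}

#' Build the ARG box model from a curated box table
#'
#' The canonical modelling pipeline: select the training boxes (flag `c`
#' excluded), and build the individual-information model from their 20-nt
#' sequences. Because the ARG box is a dyad-symmetric (palindromic) operator
#' bound by a rotationally symmetric repressor oligomer, the default counts
#' every training box on both strands, which symmetrizes the frequency
#' matrix and evaluates the small-sample correction at the number of
#' strand-oriented sequences actually counted (2n).
#'
#' @param boxes Box table (default the packaged collection).
#' @param training_only Drop flag-`c` boxes first (default `TRUE`).
#' @param both_strands Count both strands (default `TRUE`).
#' @param ... Passed to [build_model()].
#' @return An `arg_iimodel`.
#' @export
build_arg_model <- function(boxes = arg_boxes(), training_only = TRUE,
                            both_strands = TRUE, ...) {
  if (training_only) boxes <- training_boxes(boxes)
  pfm <- build_pfm(boxes$sequence, L = 20L, both_strands = both_strands)
  build_model(pfm, ...)
}

#' Serialize a model to a plain-text file
#'
#' Writes header lines (width, n, e(n), Rsequence, policy, alpha,
#' both_strands), the L x 4 weight matrix and the companion count block.
#' Doubles are written with 17 significant digits so that
#' [read_model()] round-trips bit-exactly.
#'
#' @param model An `arg_iimodel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "arg_iimodel"))
  g17 <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# argboxr individual-information model",
    paste0("width\t", model$L),
    paste0("n\t", model$n),
    paste0("both_strands\t", as.integer(isTRUE(model$pfm$both_strands))),
    paste0("e_n\t", g17(model$e_n)),
    paste0("rsequence\t", g17(model$rsequence)),
    paste0("policy\t", model$policy),
    paste0("alpha\t", g17(model$alpha)),
    paste0("# riw: position\t", paste(DNA_BASES, collapse = "\t"))
  ), con)
  for (l in seq_len(model$L)) {
    writeLines(paste(c(l, g17(model$riw[, l])), collapse = "\t"), con)
  }
  writeLines(paste0("# counts: position\t", paste(DNA_BASES, collapse = "\t")),
             con)
  for (l in seq_len(model$L)) {
    writeLines(paste(c(l, model$pfm$counts[, l]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_model()].
#' @return An `arg_iimodel`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  kv <- fields[vapply(fields, length, 0L) == 2L]
  hdr <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  L <- as.integer(hdr[["width"]])
  rows <- fields[vapply(fields, length, 0L) == 5L]
  if (length(rows) != 2L * L) {
    stop("malformed model file: expected ", 2L * L, " matrix rows",
         call. = FALSE)
  }
  riw <- vapply(rows[seq_len(L)],
                function(r) as.numeric(r[2:5]), numeric(4L))
  counts <- vapply(rows[L + seq_len(L)],
                   function(r) as.integer(r[2:5]), integer(4L))
  dimnames(riw) <- dimnames(counts) <- list(DNA_BASES, NULL)
  n <- as.integer(hdr[["n"]])
  pfm <- structure(list(counts = counts, freq = counts / n, n = n, L = L,
                        both_strands = hdr[["both_strands"]] == "1"),
                   class = "arg_pfm")
  H <- apply(pfm$freq, 2L, function(p) -sum(xlog2x(p)))
  cons_idx <- apply(pfm$freq, 2L, which.max)
  consensus <- paste(DNA_BASES[cons_idx], collapse = "")
  attr(consensus, "ties") <- which(vapply(seq_len(L), function(l) {
    sum(pfm$freq[, l] == max(pfm$freq[, l])) > 1L
  }, logical(1L)))
  structure(list(pfm = pfm, n = n, L = L,
                 e_n = as.numeric(hdr[["e_n"]]), H = H, riw = riw,
                 rsequence = as.numeric(hdr[["rsequence"]]),
                 consensus = consensus,
                 consensus_ri = sum(apply(riw, 2L, max)),
                 policy = hdr[["policy"]],
                 alpha = as.numeric(hdr[["alpha"]])),
            class = "arg_iimodel")
}
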