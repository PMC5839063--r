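#' Exact score distribution of a model under a 0-order background
#'
#' Discretizes a scoring matrix to a fixed granularity (bits per bin) and
#' convolves the per-position score distributions under independent draws
#' from the background base frequencies, yielding the exact probability mass
#' function and upper-tail of the binned score of a random L-mer. The
#' default scoring matrix is the log-odds of the model frequencies against
#' the background (`log2 f(b,l)/q(b)`), the score whose tail a
#' composition-aware scanner converts to p-values; `type = "ri"` instead
#' uses the individual-information weights (2-bit uniform reference).
#' Non-finite cells (zero-count cells under the `minus_infinity` policy)
#' are floored at the pseudocount-equivalent weight before binning.
#'
#' @param model An `arg_iimodel`.
#' @param background Numeric length-4 vector of base probabilities
#'   (A, C, G, T); default uniform.
#' @param granularity Bin width in bits (default 1e-3).
#' @param type `"log_odds"` (default) or `"ri"`.
#' @return An object of class `arg_score_dist`: list with `granularity`,
#'   `type`, `kmat` (integer-binned 4 x L scoring matrix), `offset` (bin
#'   index of the first pmf element), `pmf`, `tail` (upper-tail
#'   probabilities, same indexing), `background`, `support` (achievable
#'   min/max score in bits).
#' @export
score_distribution <- function(model, background = rep(0.25, 4L),
                               granularity = 1e-3,
                               type = c("log_odds", "ri")) {
  stopifnot(inherits(model, "arg_iimodel"))
  type <- match.arg(type)
  if (granularity <= 0) stop("granularity must be > 0", call. = FALSE)
  q <- background / sum(background)
  # pseudocount-equivalent frequency floor for never-observed cells
  f_floor <- model$alpha / (model$n + 4 * model$alpha)
  if (type == "ri") {
    W <- model$riw
    W[!is.finite(W)] <- 2 + log2(f_floor) - model$e_n
  } else {
    f <- pmax(model$pfm$freq, f_floor)
    W <- log2(sweep(f, 1L, q, "/"))
  }
  kmat <- round(W / granularity)
  if (any(abs(kmat) > .Machine$integer.max / (model$L + 1))) {
    stop("granularity too fine for the weight range", call. = FALSE)
  }
  storage.mode(kmat) <- "integer"
  kmin <- sum(apply(kmat, 2L, min))
  kmax <- sum(apply(kmat, 2L, max))
  if (kmax - kmin < 10L) {
    stop("resolution error: score support collapses to fewer than 10 bins",
         call. = FALSE)
  }
  # DP convolution over positions; pmf[i] = Pr(binned score = lo + i - 1)
  pmf <- 1
  lo <- 0L
  for (l in seq_len(model$L)) {
    ks <- kmat[, l]
    new_lo <- lo + min(ks)
    new_len <- length(pmf) + (max(ks) - min(ks))
    acc <- numeric(new_len)
    for (b in 1:4) {
      at <- ks[b] - min(ks)
      acc[(at + 1L):(at + length(pmf))] <-
        acc[(at + 1L):(at + length(pmf))] + q[b] * pmf
    }
    pmf <- acc
    lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(pmf)))
  structure(list(granularity = granularity, type = type, kmat = kmat,
                 offset = lo, pmf = pmf, tail = tail_p, background = q,
                 support = c(kmin, kmax) * granularity),
            class = "arg_score_dist")
}

# upper-tail probability of binned score >= k (integer bin index)
tail_at_bin <- function(dist, k) {
  idx <- k - dist$offset + 1L
  idx <- pmax(1L, idx)
  out <- ifelse(idx > length(dist$tail), 0, dist$tail[idx])
  out
}

#' Upper-tail p-value of a score
#'
#' `Pr(score >= s)` for a random L-mer under the distribution's background.
#' The query score is rounded down to its bin floor (conservative).
#'
#' @param dist An `arg_score_dist`.
#' @param s Score(s) in bits.
#' @return Numeric vector of p-values in (0, 1].
#' @export
pvalue <- function(dist, s) {
  stopifnot(inherits(dist, "arg_score_dist"))
  tail_at_bin(dist, floor(s / dist$granularity))
}

# binned score sums of every window on the coded sequence x (integer codes
# 1..4, NA for non-ACGT); returns integer vector of length n_win (NA where
# the window contains a non-ACGT symbol)
window_sums <- function(x, mat) {
  L <- ncol(mat)
  n_win <- length(x) - L + 1L
  if (n_win < 1L) return(numeric(0))
  s <- numeric(n_win)
  for (l in seq_len(L)) {
    s <- s + mat[, l][x[l:(l + n_win - 1L)]]
  }
  s
}

#' Scan a sequence for model hits
#'
#' Slides the model window over the sequence (both strands for asymmetric
#' models) and keeps windows passing BOTH filters: exact upper-tail p-value
#' below `p_max` and individual information above `ri_min` bits. P-values
#' are computed from the exact binned distribution of the composition-aware
#' log-odds score (`log2 f/q`) under the chosen background (the background
#' is strand-averaged); `Ri` is always reported on the unbinned
#' 2-bit-uniform scale, so scores stay comparable across scans.
#' Windows containing non-ACGT symbols are skipped (count in attribute
#' `n_skipped`). For palindrome-symmetric models the two strands give
#' identical scores at every window, so coincident opposite-strand
#' duplicates are collapsed to a single `+` hit unless
#' `collapse_palindrome = FALSE`.
#'
#' @param seqs Named character vector of sequences (names become `chrom`).
#' @param model An `arg_iimodel`.
#' @param p_max P-value filter (default 1e-5).
#' @param ri_min Ri filter in bits (default 10.0).
#' @param background `"sequence"` (0-order composition of each scanned
#'   sequence; default), `"uniform"`, or a numeric length-4 vector.
#' @param granularity Bin width for the p-value distribution.
#' @param collapse_palindrome Collapse strand-duplicate hits of symmetric
#'   models (default `TRUE`).
#' @param dist Optional precomputed `arg_score_dist` (overrides
#'   `background`/`granularity`).
#' @return Data frame of hits sorted by (chrom, left): `chrom`, `left`,
#'   `right`, `strand`, `ri`, `p_value`; attribute `n_skipped`.
#' @export
scan_sequence <- function(seqs, model, p_max = 1e-5, ri_min = 10.0,
                          background = "sequence", granularity = 1e-3,
                          collapse_palindrome = TRUE, dist = NULL) {
  stopifnot(inherits(model, "arg_iimodel"))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  W <- model$riw
  Wrc <- W[COMP_IDX, rev(seq_len(model$L)), drop = FALSE]  # minus-strand weights
  symmetric <- max(abs(ifelse(is.finite(W), W, -1e9) -
                       ifelse(is.finite(Wrc), Wrc, -1e9))) < 1e-9
  do_minus <- !(symmetric && collapse_palindrome)
  res <- vector("list", length(seqs))
  n_skipped <- 0L
  for (i in seq_along(seqs)) {
    x <- match(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]], DNA_BASES)
    if (length(x) < model$L) {
      res[[i]] <- NULL
      next
    }
    d <- dist
    if (is.null(d)) {
      q <- if (identical(background, "sequence")) {
        qi <- tabulate(x[!is.na(x)], 4L) / max(1L, sum(!is.na(x)))
        (qi + qi[COMP_IDX]) / 2  # strand-averaged composition
      } else if (identical(background, "uniform")) {
        rep(0.25, 4L)
      } else background
      if (any(q <= 0)) q <- (q + 1e-6) / sum(q + 1e-6)
      d <- score_distribution(model, background = q,
                              granularity = granularity)
    }
    # per-position lookup with non-ACGT coded as index 5 -> NA
    xc <- ifelse(is.na(x), 5L, x)
    Wp <- rbind(W, NA_real_)
    Kp <- rbind(d$kmat, NA_integer_)
    ri_plus <- window_sums(xc, Wp)
    k_plus <- window_sums(xc, Kp)
    strands <- list(`+` = list(ri = ri_plus, k = k_plus))
    if (do_minus) {
      Wrcp <- rbind(Wrc, NA_real_)
      Krc <- Kp[c(COMP_IDX, 5L), rev(seq_len(model$L)), drop = FALSE]
      strands$`-` <- list(ri = window_sums(xc, Wrcp),
                          k = window_sums(xc, Krc))
    }
    hit_rows <- list()
    for (st in names(strands)) {
      ri <- strands[[st]]$ri
      k <- strands[[st]]$k
      skipped <- is.na(ri)
      n_skipped <- n_skipped + sum(skipped)
      pv <- tail_at_bin(d, k)
      keep <- which(!skipped & ri > ri_min & pv < p_max)
      if (length(keep)) {
        hit_rows[[st]] <- data.frame(
          chrom = names(seqs)[i], left = keep,
          right = keep + model$L - 1L,
          strand = st, ri = ri[keep], p_value = pv[keep],
          stringsAsFactors = FALSE)
      }
    }
    res[[i]] <- if (length(hit_rows)) do.call(rbind, hit_rows) else NULL
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), left = integer(),
                      right = integer(), strand = character(),
                      ri = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$left, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Assemble scan hits into binding sites
#'
#' Greedy left-to-right pairing of hits on the same chromosome whose
#' inter-hit gap is 0 or 1 nt into tandem sites (either strand); remaining
#' hits become single-box sites. No hit is used twice; among three mutually
#' adjacent hits the leftmost pair is taken.
#'
#' @param hits Hit data frame sorted by coordinate (see [scan_sequence()]).
#' @return Data frame with `site_id`, `chrom`, `kind`, `gap_nt`, `left`,
#'   `right`, `n_boxes`, `combined_ri`.
#' @export
assemble_sites <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(site_id = character(), chrom = character(),
                      kind = character(), gap_nt = integer(),
                      left = integer(), right = integer(),
                      n_boxes = integer(), combined_ri = numeric(),
                      stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$chrom, hits$left), , drop = FALSE]
  rows <- list()
  for (chrom in unique(hits$chrom)) {
    h <- hits[hits$chrom == chrom, , drop = FALSE]
    i <- 1L
    while (i <= nrow(h)) {
      if (i < nrow(h)) {
        gap <- h$left[i + 1L] - h$right[i] - 1L
        if (gap %in% c(0L, 1L)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom,
            kind = if (gap == 0L) "tandem_contiguous" else "tandem_gap1",
            gap_nt = gap, left = h$left[i], right = h$right[i + 1L],
            n_boxes = 2L, combined_ri = h$ri[i] + h$ri[i + 1L],
            stringsAsFactors = FALSE)
          i <- i + 2L
          next
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, kind = "single", gap_nt = NA_integer_,
        left = h$left[i], right = h$right[i], n_boxes = 1L,
        combined_ri = h$ri[i], stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  out <- do.call(rbind, rows)
  out$site_id <- sprintf("site_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("site_id", "chrom", "kind", "gap_nt", "left", "right",
          "n_boxes", "combined_ri")]
}

#' Signed distance from a site to a gene start codon
#'
#' Counts the nucleotides between the site edge proximal to the gene (in the
#' gene's reading direction) and the base immediately before the start
#' codon. Zero means the site abuts the start codon; negative values mean
#' the site overlaps or passes it.
#'
#' @param site_left,site_right Site interval (1-based inclusive).
#' @param gene_start 1-based position of the first base of the start codon
#'   (on the gene's strand: the highest coordinate of the codon for `-`
#'   strand genes).
#' @param gene_strand `"+"` or `"-"`.
#' @return Integer distance in nt.
#' @export
distance_to_start <- function(site_left, site_right, gene_start,
                              gene_strand = "+") {
  ifelse(gene_strand == "+",
         gene_start - site_right - 1L,
         site_left - gene_start - 1L)
}

#' Associate assembled sites with downstream genes
#'
#' Each site is mapped to the nearest gene whose start codon lies downstream
#' of the site in that gene's reading direction (a site overlapping a start
#' codon reports that gene with a negative distance), plus up to `max_next`
#' further genes in the same direction.
#'
#' @param sites Data frame with `chrom`, `left`, `right` (e.g. from
#'   [assemble_sites()], with a `site_id` column).
#' @param genes Data frame with `gene_id`, `chrom`, `strand`,
#'   `start_codon` (1-based position of the first start-codon base on the
#'   gene's strand).
#' @param max_next Additional downstream genes to report (default 1).
#' @return Data frame with `site_id`, `gene_id`, `rank` (1 = nearest),
#'   `distance` (nt, signed). Sites with no downstream gene are absent.
#' @export
associate_genes <- function(sites, genes, max_next = 1L) {
  if (!"site_id" %in% names(sites)) {
    sites$site_id <- sprintf("site_%d", seq_len(nrow(sites)))
  }
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    g <- genes[genes$chrom == s$chrom, , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- distance_to_start(s$left, s$right, g$start_codon, g$strand)
    # a gene is downstream-eligible if its start codon is ahead of the site
    # edge distal to it, i.e. the site does not lie entirely past the start
    elig <- d >= -(s$right - s$left)
    g <- g[elig, , drop = FALSE]
    d <- d[elig]
    if (nrow(g) == 0L) next
    ord <- order(d)
    take <- ord[seq_len(min(1L + max_next, length(ord)))]
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = s$site_id, gene_id = g$gene_id[take],
      rank = seq_along(take), distance = d[take],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no site could be associated with a downstream gene")
    out <- data.frame(site_id = character(), gene_id = character(),
                      rank = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
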