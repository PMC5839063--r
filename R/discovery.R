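# log(exp(a) + exp(b)) without overflow
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

# complement-mirror of a 4 x w matrix (reverse-complement symmetry partner)
mirror_comp <- function(m) {
  out <- m[COMP_IDX, rev(seq_len(ncol(m))), drop = FALSE]
  dimnames(out) <- dimnames(m)
  out
}

#' Palindrome-constrained EM motif discovery
#'
#' Finds one ungapped motif in a set of sequences with a two-component
#' (motif vs 0-order background) mixture fitted by EM, in either the ZOOPS
#' occurrence model (zero or one site per sequence, site prior `gamma`) or
#' the ANR model (independent per-window occurrence with a bounded expected
#' site count). Both strands are searched. With `palindrome = TRUE` the
#' motif matrix is constrained to reverse-complement symmetry by averaging
#' with its complement-mirror at every M-step (a constrained maximization,
#' so EM monotonicity is preserved). With `discriminative = TRUE` the
#' background base composition is estimated from the negative set rather
#' than from the input sequences themselves.
#'
#' Each width in `width_min:width_max` is fitted from `n_starts`
#' deterministic seed windows (the most background-improbable windows) plus
#' one seeded random start; the best width is chosen by the penalized
#' log-likelihood ratio (3 free parameters per column). The tracked
#' objective is the Dirichlet-regularized log posterior that the M-step
#' maximizes, so it is non-decreasing over iterations by construction; its
#' per-iteration minimum increment over all runs is returned for checking.
#'
#' @param positives Named character vector of sequences to search.
#' @param negatives Optional named character vector (background set).
#' @param width_min,width_max Motif width range (nt).
#' @param mode `"zoops"` or `"anr"`.
#' @param palindrome Constrain the motif to dyad symmetry (default `TRUE`).
#' @param discriminative Estimate background from `negatives`
#'   (default: `TRUE` when negatives are supplied).
#' @param max_iter,tol EM stopping rule (iterations / objective increment).
#' @param n_starts Deterministic seed windows per width.
#' @param seed Integer seed (drives the one random start; the fit is
#'   bit-reproducible for fixed inputs and seed).
#' @param gamma0 Initial ZOOPS site prior.
#' @param anr_max_sites Bound on the expected ANR site count per sequence.
#' @param pseudo Total Dirichlet pseudocount mass per motif column.
#' @return An object of class `arg_motif`: list with `width`, `freq`
#'   (4 x width motif matrix), `site_calls` (data frame `seq_id`, `offset`,
#'   `strand`, `posterior`), `consensus`, `llr`, `selection` (per-width
#'   scores), `trace` (objective trajectory of the winning run),
#'   `min_trace_delta` (smallest per-iteration objective increment over all
#'   runs), `background`, `mode`, `palindrome`, `seed`.
#' @export
em_discover <- function(positives, negatives = NULL,
                        width_min = 14L, width_max = 20L,
                        mode = c("zoops", "anr"), palindrome = TRUE,
                        discriminative = !is.null(negatives),
                        max_iter = 200L, tol = 1e-6, n_starts = 5L,
                        seed = 1L, gamma0 = 0.5, anr_max_sites = 2,
                        pseudo = 0.5) {
  mode <- match.arg(mode)
  if (length(positives) < 2L) {
    stop("need at least 2 positive sequences", call. = FALSE)
  }
  if (any(nchar(positives) < width_max)) {
    stop("input error: all sequences must be at least width_max (",
         width_max, ") nt long", call. = FALSE)
  }
  if (is.null(names(positives))) {
    names(positives) <- paste0("seq", seq_along(positives))
  }
  xs <- lapply(positives, function(s)
    match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES))
  if (anyNA(unlist(xs))) {
    stop("alphabet error: sequences must contain only A, C, G, T",
         call. = FALSE)
  }
  bg_src <- if (discriminative && !is.null(negatives)) negatives else positives
  bg_codes <- unlist(lapply(bg_src, function(s)
    match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES)))
  q <- tabulate(bg_codes[!is.na(bg_codes)], 4L)
  q <- (q + 1) / sum(q + 1)
  q <- (q + q[COMP_IDX]) / 2   # strand-averaged: both strands are searched

  with_local_seed(seed, {
    widths <- seq.int(width_min, width_max)
    per_width <- vector("list", length(widths))
    min_delta <- Inf
    for (wi in seq_along(widths)) {
      w <- widths[wi]
      starts <- em_seed_windows(xs, w, q, n_starts)
      best <- NULL
      for (st in starts) {
        fit <- em_fit(xs, w, q, st, mode, palindrome, max_iter, tol,
                      gamma0, anr_max_sites, pseudo)
        min_delta <- min(min_delta, fit$min_delta)
        if (is.null(best) || fit$objective > best$objective) best <- fit
      }
      best <- em_shift_refine(best, xs, w, q, mode, palindrome, max_iter,
                              tol, gamma0, anr_max_sites, pseudo)
      min_delta <- min(min_delta, best$min_delta)
      n_win <- sum(vapply(xs, length, 0L) - w + 1L) * 2L
      best$score <- best$llr - 0.5 * 3 * w * log(n_win)
      per_width[[wi]] <- best
    }
    scores <- vapply(per_width, `[[`, 0, "score")
    pick <- which.max(scores)
    fit <- per_width[[pick]]
    calls <- em_site_calls(fit, xs, mode)
    cons <- paste(DNA_BASES[apply(fit$f, 2L, which.max)], collapse = "")
    structure(list(width = widths[pick], freq = fit$f, site_calls = calls,
                   consensus = cons, llr = fit$llr,
                   selection = data.frame(width = widths,
                                          llr = vapply(per_width, `[[`, 0, "llr"),
                                          score = scores),
                   trace = fit$trace, min_trace_delta = min_delta,
                   background = q, mode = mode, palindrome = palindrome,
                   seed = seed),
              class = "arg_motif")
  })
}

# deterministic seed windows: the n most background-improbable distinct
# windows, plus one uniformly random window
em_seed_windows <- function(xs, w, q, n_starts) {
  logq <- log(q)
  cand <- list()
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    m <- length(x) - w + 1L
    sc <- -window_sums(x, rbind(matrix(logq, 4L, w), NA_real_))
    for (j in seq_len(m)) {
      cand[[length(cand) + 1L]] <- list(i = i, j = j, score = sc[j])
    }
  }
  sc <- vapply(cand, `[[`, 0, "score")
  ord <- order(-sc, vapply(cand, `[[`, 0L, "i"), vapply(cand, `[[`, 0L, "j"))
  seen <- character(0)
  picked <- list()
  for (k in ord) {
    x <- xs[[cand[[k]]$i]]
    sub <- paste(x[cand[[k]]$j:(cand[[k]]$j + w - 1L)], collapse = "")
    if (sub %in% seen) next
    seen <- c(seen, sub)
    picked[[length(picked) + 1L]] <- cand[[k]]
    if (length(picked) >= n_starts) break
  }
  rnd <- cand[[sample.int(length(cand), 1L)]]
  c(picked, list(rnd))
}

# initial motif matrix from a seed window (match probability 0.7)
em_init_f <- function(xs, w, q, st, palindrome) {
  x <- xs[[st$i]][st$j:(st$j + w - 1L)]
  f <- matrix(rep(q * 0.3 / 1, w), 4L, w)
  f <- sweep(f, 2L, colSums(f), "/") * 0.3
  f[cbind(x, seq_len(w))] <- f[cbind(x, seq_len(w))] + 0.7
  f <- sweep(f, 2L, colSums(f), "/")
  if (palindrome) {
    f <- (f + mirror_comp(f)) / 2
  }
  f
}

# shift motif columns by s, refilling vacated columns with the background
shift_cols <- function(f, s, q) {
  w <- ncol(f)
  out <- matrix(q, 4L, w)
  src <- seq_len(w) + s
  ok <- src >= 1L & src <= w
  out[, ok] <- f[, src[ok]]
  out
}

# one EM run from a seed window
em_fit <- function(xs, w, q, st, mode, palindrome, max_iter, tol,
                   gamma0, anr_max_sites, pseudo) {
  f0 <- em_init_f(xs, w, q, st, palindrome)
  em_run(xs, w, q, f0, mode, palindrome, max_iter, tol,
         gamma0, anr_max_sites, pseudo)
}

# register (column-shift) refinement: the palindrome constraint creates
# phase-shifted local optima, so rerun EM from column-shifted versions of a
# converged motif and adopt any restart that improves the objective
em_shift_refine <- function(fit, xs, w, q, mode, palindrome, max_iter, tol,
                            gamma0, anr_max_sites, pseudo, shift_range = 3L) {
  for (round in seq_len(4L)) {
    improved <- FALSE
    for (s in setdiff(seq.int(-shift_range, shift_range), 0L)) {
      f_s <- shift_cols(fit$f, s, q)
      # keep the start inside the constraint set: monotonicity of the
      # constrained M-step requires a symmetric starting matrix
      if (palindrome) f_s <- (f_s + mirror_comp(f_s)) / 2
      cand <- em_run(xs, w, q, f_s, mode, palindrome,
                     max_iter, tol, gamma0, anr_max_sites, pseudo)
      min_d <- min(fit$min_delta, cand$min_delta)
      if (cand$objective > fit$objective + 1e-9) {
        fit <- cand
        improved <- TRUE
      }
      fit$min_delta <- min_d
      if (improved) break
    }
    if (!improved) break
  }
  fit
}

em_run <- function(xs, w, q, f, mode, palindrome, max_iter, tol,
                   gamma0, anr_max_sites, pseudo) {
  n <- length(xs)
  m <- vapply(xs, length, 0L) - w + 1L
  a <- matrix(pseudo * q, 4L, w)           # Dirichlet pseudocounts
  if (palindrome) a <- (a + mirror_comp(a)) / 2
  gamma <- gamma0
  lambda <- min(0.5 / mean(m), anr_max_sites / (2 * mean(m)))
  trace <- numeric(0)
  min_delta <- Inf
  zs <- NULL
  for (iter in seq_len(max_iter)) {
    lw <- log(f) - matrix(log(q), 4L, w)
    lwp <- rbind(lw, NA_real_)
    lwm <- rbind(mirror_comp(lw), NA_real_)
    obj <- 0
    counts_p <- matrix(0, 4L, w)   # plus-strand genomic-frame counts
    counts_m <- matrix(0, 4L, w)   # minus-strand genomic-frame counts
    zs <- vector("list", n)
    for (i in seq_len(n)) {
      x <- xs[[i]]
      llr_p <- window_sums(x, lwp)
      llr_m <- window_sums(x, lwm)
      llr <- c(llr_p, llr_m)
      if (mode == "zoops") {
        M <- max(llr)
        logS <- M + log(sum(exp(llr - M)))
        A <- log(gamma / (2 * m[i])) + logS
        log_denom <- logaddexp(log1p(-gamma), A)
        z <- exp(log(gamma / (2 * m[i])) + llr - log_denom)
        obj <- obj + log_denom
      } else {
        eta <- log(lambda / (1 - lambda))
        z <- stats::plogis(llr + eta)
        obj <- obj + sum(log1p(-lambda) + log1pexp(llr + eta))
      }
      zp <- z[seq_len(m[i])]
      zm <- z[m[i] + seq_len(m[i])]
      for (l in seq_len(w)) {
        seg <- x[l:(l + m[i] - 1L)]
        counts_p[, l] <- counts_p[, l] + vapply(1:4, function(b)
          sum(zp[seg == b]), 0)
        counts_m[, l] <- counts_m[, l] + vapply(1:4, function(b)
          sum(zm[seg == b]), 0)
      }
      zs[[i]] <- list(zp = zp, zm = zm)
    }
    counts <- counts_p + mirror_comp(counts_m) + a
    if (palindrome) counts <- (counts + mirror_comp(counts)) / 2
    f_new <- sweep(counts, 2L, colSums(counts), "/")
    obj <- obj + sum(a * log(f))
    if (length(trace)) min_delta <- min(min_delta, obj - trace[length(trace)])
    trace <- c(trace, obj)
    converged <- length(trace) > 1L &&
      abs(trace[length(trace)] - trace[length(trace) - 1L]) < tol
    f <- f_new
    if (mode == "zoops") {
      gamma <- min(0.999, max(1e-6,
        mean(vapply(zs, function(z) sum(z$zp) + sum(z$zm), 0))))
    } else {
      tot_z <- sum(vapply(zs, function(z) sum(z$zp) + sum(z$zm), 0))
      lambda <- min(max(tot_z / (2 * sum(m)), 1e-8),
                    anr_max_sites / (2 * mean(m)))
    }
    if (converged) break
  }
  llr0 <- sum(a * log(matrix(q, 4L, w)))
  list(f = f, objective = trace[length(trace)],
       llr = trace[length(trace)] - llr0, trace = trace,
       min_delta = if (is.finite(min_delta)) min_delta else 0,
       zs = zs, w = w, gamma = gamma, lambda = lambda)
}

# final site calls from posteriors
em_site_calls <- function(fit, xs, mode) {
  rows <- list()
  for (i in seq_along(xs)) {
    zp <- fit$zs[[i]]$zp
    zm <- fit$zs[[i]]$zm
    if (mode == "zoops") {
      if (sum(zp) + sum(zm) <= 0.5) next
      if (max(zp) >= max(zm)) {
        j <- which.max(zp); strand <- "+"; post <- zp[j]
      } else {
        j <- which.max(zm); strand <- "-"; post <- zm[j]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = names(xs)[i], offset = j, strand = strand,
        posterior = post, stringsAsFactors = FALSE)
    } else {
      z <- c(zp, zm)
      strand <- rep(c("+", "-"), c(length(zp), length(zm)))
      off <- c(seq_along(zp), seq_along(zm))
      ord <- order(-z)
      used <- logical(0)
      taken_iv <- matrix(numeric(0), ncol = 2L)
      for (k in ord) {
        if (z[k] <= 0.5) break
        iv <- c(off[k], off[k] + fit$w - 1L)
        if (nrow(taken_iv) == 0L ||
            all(iv[1L] > taken_iv[, 2L] | iv[2L] < taken_iv[, 1L])) {
          taken_iv <- rbind(taken_iv, iv)
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = names(xs)[i], offset = off[k], strand = strand[k],
            posterior = z[k], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), offset = integer(),
                      strand = character(), posterior = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$seq_id, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the called motif windows as an alignment
#'
#' Pulls the called windows out of the sequences (reverse-complemented for
#' minus-strand calls), producing a uniform-width alignment ready for
#' [build_pfm()].
#'
#' @param motif An `arg_motif` from [em_discover()].
#' @param seqs The sequences the motif was discovered in.
#' @return Character vector of aligned windows (named by sequence id).
#' @export
site_calls_to_alignment <- function(motif, seqs) {
  calls <- motif$site_calls
  out <- character(nrow(calls))
  for (k in seq_len(nrow(calls))) {
    s <- seqs[[calls$seq_id[k]]]
    j <- calls$offset[k]
    if (j < 1L || j + motif$width - 1L > nchar(s)) {
      stop("geometry error: site call outside sequence bounds", call. = FALSE)
    }
    win <- substr(s, j, j + motif$width - 1L)
    out[k] <- if (calls$strand[k] == "-") reverse_complement(win) else win
  }
  stats::setNames(out, calls$seq_id)
}
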