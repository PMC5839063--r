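# All generators take an explicit `seed` and restore the caller's RNG state,
# so synthetic data are bit-reproducible (Mersenne-Twister / Inversion).
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(code)
}

#' Generate an i.i.d. background genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`. The default GC content emulates a
#' *Streptomyces*-like high-GC chromosome.
#'
#' @param length Genome length in nt.
#' @param gc GC fraction in (0, 1); default 0.72.
#' @param seed Integer seed (fixed-seed runs are bit-reproducible).
#' @param id Sequence name.
#' @return Named character vector of length 1.
#' @export
generate_background <- function(length, gc = 0.72, seed = 1L,
                                id = "synthetic") {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  q <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_local_seed(seed, {
    x <- sample.int(4L, size = length, replace = TRUE, prob = q)
    stats::setNames(paste(DNA_BASES[x], collapse = ""), id)
  })
}

# sample one box sequence from the model's frequency matrix, optionally
# rejection-sampled to a target Ri (bits)
sample_box <- function(model, ri_target = NULL, ri_tol = 0.5,
                       max_tries = 1e5L) {
  f <- model$pfm$freq
  draw <- function() {
    idx <- vapply(seq_len(model$L),
                  function(l) sample.int(4L, 1L, prob = f[, l]), integer(1L))
    paste(DNA_BASES[idx], collapse = "")
  }
  if (is.null(ri_target)) return(draw())
  for (i in seq_len(max_tries)) {
    s <- draw()
    ri <- unname(ri_score(model, s))
    if (is.finite(ri) && abs(ri - ri_target) <= ri_tol) return(s)
  }
  stop("could not sample a box with Ri within ", ri_tol, " of ", ri_target,
       " in ", max_tries, " tries", call. = FALSE)
}

#' Plant binding sites into a background sequence
#'
#' Places `n_sites` non-overlapping sites (single boxes or two-box tandems
#' with a 0- or 1-nt gap) at positions at least `min_spacing` nt apart, on
#' random strands. Box sequences are sampled per-position from the model's
#' frequency matrix, or rejection-sampled to a fixed Ri target.
#'
#' @param background Named character vector of length 1 (the genome).
#' @param model An `arg_iimodel` supplying box width and frequencies.
#' @param n_sites Number of sites to plant.
#' @param architecture_mix Named proportions over
#'   `single`, `tandem_contiguous`, `tandem_gap1` (default all single).
#' @param ri_target Optional fixed Ri target in bits (per box); `NULL`
#'   samples directly from the frequency matrix.
#' @param ri_tol Tolerance around `ri_target` (default 0.5 bits).
#' @param min_spacing Minimum nt between planted sites (default 50).
#' @param seed Integer seed.
#' @param max_tries Placement/rejection attempt bound.
#' @return List with `sequence` (the genome with sites written in) and
#'   `truth`: data frame `site_id`, `architecture`, `left`, `right`,
#'   `strand`, `gap_nt`, `box1_seq`, `box2_seq`, `box1_ri`, `box2_ri`.
#' @export
plant_sites <- function(background, model, n_sites,
                        architecture_mix = c(single = 1,
                                             tandem_contiguous = 0,
                                             tandem_gap1 = 0),
                        ri_target = NULL, ri_tol = 0.5, min_spacing = 50L,
                        seed = 1L, max_tries = 1e5L) {
  stopifnot(length(background) == 1L)
  mix <- architecture_mix / sum(architecture_mix)
  glen <- nchar(background[[1L]])
  L <- model$L
  site_span <- 2L * L + 1L  # widest architecture
  if (n_sites * (site_span + min_spacing) > glen) {
    stop("placement error: ", n_sites, " sites do not fit in ", glen, " nt",
         call. = FALSE)
  }
  with_local_seed(seed, {
    kinds <- sample(names(mix), n_sites, replace = TRUE, prob = mix)
    spans <- ifelse(kinds == "single", L,
                    ifelse(kinds == "tandem_contiguous", 2L * L, 2L * L + 1L))
    lefts <- integer(0)
    for (i in seq_len(n_sites)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- sample.int(glen - spans[i] + 1L, 1L)
        if (all(abs(cand - lefts) >= site_span + min_spacing)) {
          lefts <- c(lefts, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement error after ", max_tries, " tries",
                        call. = FALSE)
    }
    chars <- strsplit(background[[1L]], "", fixed = TRUE)[[1L]]
    truth <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      b1 <- sample_box(model, ri_target, ri_tol, max_tries)
      b2 <- if (kinds[i] == "single") NA_character_
            else sample_box(model, ri_target, ri_tol, max_tries)
      gap <- switch(kinds[i], single = NA_integer_,
                    tandem_contiguous = 0L, tandem_gap1 = 1L)
      insert <- if (is.na(b2)) b1 else {
        paste0(b1, strrep("N", 0), if (gap == 1L)
          sample(DNA_BASES, 1L) else "", b2)
      }
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "+") insert else reverse_complement(insert)
      pos <- lefts[i]
      chars[pos:(pos + nchar(written) - 1L)] <-
        strsplit(written, "", fixed = TRUE)[[1L]]
      truth[[i]] <- data.frame(
        site_id = sprintf("planted_%d", i), architecture = kinds[i],
        left = pos, right = pos + nchar(written) - 1L, strand = strand,
        gap_nt = gap, box1_seq = b1, box2_seq = b2,
        box1_ri = unname(ri_score(model, b1)),
        box2_ri = if (is.na(b2)) NA_real_ else unname(ri_score(model, b2)),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$left), , drop = FALSE]
    rownames(truth) <- NULL
    list(sequence = stats::setNames(paste(chars, collapse = ""),
                                    names(background)),
         truth = truth)
  })
}

#' Generate labeled positive/negative probe sets
#'
#' Emulates a band-shift probe collection: positives are background probes
#' carrying one planted box (or a two-box tandem with probability
#' `tandem_prob`), negatives are pure background of matched length and
#' composition.
#'
#' @param model An `arg_iimodel`.
#' @param n_pos,n_neg Number of positive / negative probes (defaults 30/20).
#' @param probe_len Probe length in nt (default 100).
#' @param tandem_prob Probability that a positive probe carries a contiguous
#'   two-box tandem (default 0).
#' @param gc Background GC fraction (default 0.72).
#' @param ri_target,ri_tol Optional per-box Ri target (see [plant_sites()]).
#' @param seed Integer seed.
#' @return List with `positives`, `negatives` (named character vectors) and
#'   `truth` (data frame `probe_id`, `offset`, `strand`, `n_boxes`,
#'   `box1_seq`, `box2_seq`).
#' @export
generate_probe_sets <- function(model, n_pos = 30L, n_neg = 20L,
                                probe_len = 100L, tandem_prob = 0,
                                gc = 0.72, ri_target = NULL, ri_tol = 0.5,
                                seed = 1L) {
  L <- model$L
  if (probe_len < 2L * L + 1L) {
    stop("probe_len must be at least ", 2L * L + 1L, call. = FALSE)
  }
  q <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_local_seed(seed, {
    mk_bg <- function() paste(
      DNA_BASES[sample.int(4L, probe_len, replace = TRUE, prob = q)],
      collapse = "")
    truth <- vector("list", n_pos)
    positives <- character(n_pos)
    for (i in seq_len(n_pos)) {
      bg <- mk_bg()
      two <- stats::runif(1L) < tandem_prob
      b1 <- sample_box(model, ri_target, ri_tol)
      b2 <- if (two) sample_box(model, ri_target, ri_tol) else NA_character_
      ins <- if (two) paste0(b1, b2) else b1
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "+") ins else reverse_complement(ins)
      off <- sample.int(probe_len - nchar(written) + 1L, 1L)
      substr(bg, off, off + nchar(written) - 1L) <- written
      positives[i] <- bg
      truth[[i]] <- data.frame(
        probe_id = sprintf("pos_%d", i), offset = off, strand = strand,
        n_boxes = if (two) 2L else 1L, box1_seq = b1, box2_seq = b2,
        stringsAsFactors = FALSE)
    }
    names(positives) <- sprintf("pos_%d", seq_len(n_pos))
    negatives <- stats::setNames(
      vapply(seq_len(n_neg), function(i) mk_bg(), ""),
      sprintf("neg_%d", seq_len(n_neg)))
    list(positives = positives, negatives = negatives,
         truth = do.call(rbind, truth))
  })
}

#' Sensitivity and precision of a scan against a planted truth set
#'
#' A planted site counts as recovered (true positive) if at least one hit
#' overlaps it by at least `min_overlap` nt; a hit not overlapping any
#' planted site by that much is a false positive.
#'
#' @param hits Hit data frame from [scan_sequence()].
#' @param truth Truth data frame from [plant_sites()].
#' @param min_overlap Minimum overlap in nt (default 10).
#' @return List with `sensitivity`, `precision`, `n_truth`, `n_hits`,
#'   `by_architecture` (per-architecture sensitivity data frame).
#' @export
evaluate_scan <- function(hits, truth, min_overlap = 10L) {
  overlaps <- function(l1, r1, l2, r2) {
    pmin(r1, r2) - pmax(l1, l2) + 1L >= min_overlap
  }
  hit_tp <- logical(nrow(hits))
  truth_found <- logical(nrow(truth))
  for (j in seq_len(nrow(truth))) {
    ov <- overlaps(hits$left, hits$right, truth$left[j], truth$right[j])
    if (any(ov)) {
      truth_found[j] <- TRUE
      hit_tp[ov] <- TRUE
    }
  }
  by_arch <- NULL
  if (nrow(truth) > 0L) {
    by_arch <- stats::aggregate(truth_found,
                                by = list(architecture = truth$architecture),
                                FUN = mean)
    names(by_arch)[2L] <- "sensitivity"
  }
  list(sensitivity = if (nrow(truth)) mean(truth_found) else NA_real_,
       precision = if (nrow(hits)) mean(hit_tp) else NA_real_,
       n_truth = nrow(truth), n_hits = nrow(hits),
       by_architecture = by_arch)
}
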