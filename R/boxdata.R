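#' Curated ARG box collection
#'
#' Loads the packaged table of 44 experimentally supported ArgR binding boxes
#' (20-nt sequences with 1-based inclusive chromosomal coordinates on the
#' *S. coelicolor* chromosome, the distance from the box to the start codon
#' of the regulated gene(s), the published per-box information score in bits,
#' and curation flags). Flag letters:
#'
#' * `a` - no separation between the two boxes of a tandem site
#' * `b` - one-nucleotide separation between the boxes
#' * `c` - box excluded from the training alignment
#' * `d` - site may control two divergent genes
#' * `e` - an alternative box lies 27 nt upstream
#' * `f` - differential transcription not observed
#'
#' Dual distances for bidirectional promoters are kept verbatim (e.g.
#' `"18|-3"`) in `distance` and parsed into `distance_1`/`distance_2`.
#'
#' @param path Path to a box table in the same TSV dialect; defaults to the
#'   packaged fixture.
#' @return Data frame with one row per box: `gene_code`, `gene_name`,
#'   `box_id`, `sequence`, `left`, `right`, `distance`, `distance_1`,
#'   `distance_2`, `printed_ri`, `flags`.
#' @export
arg_boxes <- function(path = system.file("extdata", "arg_boxes.tsv",
                                         package = "argboxr")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("box table not found: ", path, call. = FALSE)
  }
  x <- utils::read.delim(path, colClasses = "character", fill = TRUE,
                         quote = "", na.strings = NULL)
  need <- c("gene_code", "gene_name", "box_id", "sequence", "left", "right",
            "distance", "ri", "flags")
  if (!all(need %in% names(x))) {
    stop("box table is missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  x$flags[is.na(x$flags)] <- ""
  dist <- strsplit(x$distance, "|", fixed = TRUE)
  out <- data.frame(
    gene_code  = x$gene_code,
    gene_name  = x$gene_name,
    box_id     = x$box_id,
    sequence   = toupper(x$sequence),
    left       = as.integer(x$left),
    right      = as.integer(x$right),
    distance   = x$distance,
    distance_1 = as.integer(vapply(dist, `[`, "", 1L)),
    distance_2 = as.integer(vapply(dist, function(d) d[2L], "")),
    printed_ri = as.numeric(x$ri),
    flags      = x$flags,
    stringsAsFactors = FALSE
  )
  bad <- which(nchar(out$sequence) != interval_length(out$left, out$right))
  if (length(bad)) {
    stop("box sequence length does not match its interval for: ",
         paste(out$box_id[bad], collapse = ", "), call. = FALSE)
  }
  if (grepl("arg_boxes.tsv", path, fixed = TRUE)) {
    # packaged fixture integrity: fixed content hash and curation counts
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, ARG_BOX_FIXTURE_MD5)) {
      stop("packaged ARG box fixture failed its integrity check", call. = FALSE)
    }
    stopifnot(nrow(out) == 44L, sum(grepl("c", out$flags, fixed = TRUE)) == 7L)
  }
  out
}

# md5 of the packaged fixture; regenerated only when the table itself changes
ARG_BOX_FIXTURE_MD5 <- "9d323c74bc79413fc1a9480758ca53b7"

#' Select the training subset of a box table
#'
#' Drops boxes whose curation flags contain `c` (excluded from the model).
#' On the packaged 44-box collection this yields the 37-box training set.
#'
#' @param boxes Data frame from [arg_boxes()].
#' @return The subset of rows not flagged `c`, order preserved.
#' @export
training_boxes <- function(boxes) {
  if (!all(c("box_id", "flags") %in% names(boxes))) {
    stop("boxes must have 'box_id' and 'flags' columns", call. = FALSE)
  }
  keep <- !grepl("c", boxes$flags, fixed = TRUE)
  boxes[keep, , drop = FALSE]
}

# grouping key: everything before the final "_"; the trailing suffix
# (_1/_2, _A0, _B1...) indexes boxes within a locus
box_site_key <- function(box_id) {
  sub("_[^_]*$", "", box_id)
}

#' Classify binding-site architectures from box coordinates
#'
#' Groups boxes into candidate sites and classifies each site purely from the
#' coordinates: two boxes separated by 0 nt form a contiguous tandem, by 1 nt
#' a one-nucleotide-gap tandem, a lone box a single-box site, and two
#' neighbouring boxes at any larger separation a `paired_other` site with the
#' gap recorded. Within a group, boxes are paired greedily left to right.
#'
#' @param boxes Data frame with `box_id`, `left`, `right` (and `gene_code`).
#' @param grouping `"box_id"` (default; trailing-index structure of the box
#'   identifiers) or `"distance"` (purely geometric: boxes closer than
#'   `max_dist` nt are grouped, for tables without structured ids).
#' @param max_dist Grouping distance for `grouping = "distance"`.
#' @return Data frame with one row per site: `site_id`, `kind`
#'   (`single`, `tandem_contiguous`, `tandem_gap1`, `paired_other`),
#'   `gap_nt` (NA for singles), `box_1`, `box_2`, `left`, `right`.
#' @export
classify_architecture <- function(boxes, grouping = c("box_id", "distance"),
                                  max_dist = 25L) {
  grouping <- match.arg(grouping)
  b <- boxes[order(boxes$left), , drop = FALSE]
  if (grouping == "box_id") {
    key <- box_site_key(b$box_id)
  } else {
    # chain boxes whose gap to the previous box is < max_dist
    gap_prev <- c(Inf, b$left[-1L] - b$right[-nrow(b)] - 1L)
    key <- cumsum(gap_prev >= max_dist)
  }
  res <- lapply(split(seq_len(nrow(b)), key), function(idx) {
    g <- b[idx, , drop = FALSE]
    n <- nrow(g)
    rows <- list()
    i <- 1L
    while (i <= n) {
      if (i < n) {
        gap <- g$left[i + 1L] - g$right[i] - 1L
        if (gap < 0L) {
          stop("overlapping boxes within a site group: ",
               g$box_id[i], " / ", g$box_id[i + 1L], call. = FALSE)
        }
        pair_kind <- if (gap == 0L) "tandem_contiguous"
                     else if (gap == 1L) "tandem_gap1"
                     else if (n == 2L) "paired_other"
                     else NA_character_
        if (!is.na(pair_kind)) {
          rows[[length(rows) + 1L]] <- data.frame(
            kind = pair_kind, gap_nt = gap,
            box_1 = g$box_id[i], box_2 = g$box_id[i + 1L],
            left = g$left[i], right = g$right[i + 1L],
            stringsAsFactors = FALSE)
          i <- i + 2L
          next
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "single", gap_nt = NA_integer_,
        box_1 = g$box_id[i], box_2 = NA_character_,
        left = g$left[i], right = g$right[i],
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$left), , drop = FALSE]
  out$site_id <- paste0("site.", out$box_1)
  rownames(out) <- NULL
  out[, c("site_id", "kind", "gap_nt", "box_1", "box_2", "left", "right")]
}

#' Concordance between tandem footnote flags and box geometry
#'
#' For every classified two-box site whose first box carries an `a` or `b`
#' flag, reports the flag-implied gap (0 for `a`, 1 for `b`) against the
#' coordinate-derived gap.
#'
#' @param boxes Data frame from [arg_boxes()].
#' @return Data frame with `site_id`, `flag`, `expected_gap`, `observed_gap`,
#'   `concordant`.
#' @export
flag_geometry_concordance <- function(boxes) {
  arch <- classify_architecture(boxes)
  arch <- arch[!is.na(arch$gap_nt), , drop = FALSE]
  flag1 <- boxes$flags[match(arch$box_1, boxes$box_id)]
  has_a <- grepl("a", flag1, fixed = TRUE)
  has_b <- grepl("b", flag1, fixed = TRUE)
  keep <- has_a | has_b
  data.frame(
    site_id = arch$site_id[keep],
    flag = ifelse(has_a[keep], "a", "b"),
    expected_gap = ifelse(has_a[keep], 0L, 1L),
    observed_gap = arch$gap_nt[keep],
    concordant = ifelse(has_a[keep], 0L, 1L) == arch$gap_nt[keep],
    stringsAsFactors = FALSE
  )
}
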