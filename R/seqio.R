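#' Read a FASTA file
#'
#' Reads DNA sequences and canonicalizes residues to uppercase. Sequences are
#' returned as a named character vector (names are the FASTA ids, i.e. the
#' header up to the first whitespace), in file order.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of one or more DNA strings. IUPAC
#' ambiguity codes (including N) are complemented; any other symbol is an
#' error.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  out <- tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))),
    error = function(e) stop("non-nucleotide symbol in sequence: ",
                             conditionMessage(e), call. = FALSE)
  )
  names(out) <- names(x)
  out
}

#' Length of a 1-based inclusive genomic interval
#'
#' @param left,right Integer vectors of 1-based inclusive endpoints.
#' @return Integer vector `right - left + 1`.
#' @export
interval_length <- function(left, right) {
  if (any(right < left)) {
    stop("invalid interval: right < left", call. = FALSE)
  }
  as.integer(right - left + 1L)
}

# canonical, deterministic number formatting for hit files
fmt_num <- function(x, digits = 6L) {
  sprintf(paste0("%.", digits, "g"), x)
}

#' Write scan hits to BED6 or GFF3
#'
#' Hits are written sorted by (chrom, left). BED output is 0-based
#' half-open with the score column holding `round(Ri * 100)`; GFF3 output is
#' 1-based inclusive with `Ri` and `pvalue` attributes.
#'
#' @param hits Data frame with columns `chrom`, `left`, `right`, `strand`,
#'   `ri`, `p_value` (as returned by [scan_sequence()]).
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  need <- c("chrom", "left", "right", "strand", "ri", "p_value")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  hits <- hits[order(hits$chrom, hits$left), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bed") {
    writeLines('track name="argboxr_hits"', con)
    if (nrow(hits) > 0L) {
      lines <- paste(hits$chrom,
                     hits$left - 1L,
                     hits$right,
                     sprintf("hit_%d", seq_len(nrow(hits))),
                     round(hits$ri * 100),
                     hits$strand,
                     sep = "\t")
      writeLines(lines, con)
    }
  } else {
    writeLines("##gff-version 3", con)
    if (nrow(hits) > 0L) {
      attrs <- sprintf("ID=hit_%d;Ri=%s;pvalue=%s",
                       seq_len(nrow(hits)),
                       fmt_num(hits$ri), fmt_num(hits$p_value))
      lines <- paste(hits$chrom, "argboxr", "binding_site",
                     hits$left, hits$right,
                     fmt_num(hits$ri), hits$strand, ".", attrs,
                     sep = "\t")
      writeLines(lines, con)
    }
  }
  invisible(path)
}
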