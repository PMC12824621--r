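#' File input/output for the standard evidence formats
#'
#' Writers emit plain-text, tab-separated files in the conventions used
#' throughout the package: BED/bedGraph/BEDPE coordinates are 0-based
#' half-open and headerless; auxiliary tables (sites, allele observations,
#' CNV calls) are TSV with a header. Each reader is the exact inverse of its
#' writer.
#'
#' @name duptrp-io
NULL

#' @describeIn duptrp-io Write depth bins as a 4-column bedGraph-like TSV.
#' @param bins,path data and file path.
#' @export
write_depth_tsv <- function(bins, path) {
  utils::write.table(bins[, c("chrom", "start", "end", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @describeIn duptrp-io Read depth bins written by [write_depth_tsv()].
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "count"),
                          colClasses = c("character", "integer", "integer",
                                         "integer"))
  if (nrow(df) == 0L) stop("no depth bins in ", path)
  df[order(df$chrom, df$start), , drop = FALSE]
}

BEDPE_COLS <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                "name", "score", "strand1", "strand2")

#' @describeIn duptrp-io Write junction evidence as 10-column BEDPE.
#' @param bedpe BEDPE data.frame.
#' @export
write_bedpe <- function(bedpe, path) {
  utils::write.table(bedpe[, BEDPE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn duptrp-io Read a 10-column BEDPE file; malformed rows are
#'   reported with their line number and either skipped or fatal.
#' @param strict if `TRUE` (default), malformed rows abort; otherwise they are
#'   skipped with a warning.
#' @export
read_bedpe <- function(path, strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      name = character(0), score = integer(0),
                      strand1 = character(0), strand2 = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) {
    length(p) < 10L || !all(p[c(9, 10)] %in% c("+", "-")) ||
      anyNA(suppressWarnings(as.integer(p[c(2, 3, 5, 6)])))
  }, logical(1)))
  if (length(bad)) {
    msg <- paste0("malformed BEDPE row(s) at line(s): ",
                  paste(bad, collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; skipped")
    parts <- parts[-bad]
  }
  df <- as.data.frame(do.call(rbind, lapply(parts, `[`, 1:10)),
                      stringsAsFactors = FALSE)
  names(df) <- BEDPE_COLS
  for (col in c("start1", "end1", "start2", "end2", "score")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' @describeIn duptrp-io Write intervals (e.g. layout, genes, CN segments) as
#'   BED; any columns beyond chrom/start/end become extra BED fields.
#' @param bed data.frame whose first columns are `chrom`, `start`, `end` (or
#'   a layout with `id` which is placed in the BED name field).
#' @export
write_bed <- function(bed, path) {
  if (!"chrom" %in% names(bed) && all(c("id", "start", "end") %in% names(bed))) {
    bed <- data.frame(chrom = "chrSim", start = bed$start, end = bed$end,
                      name = bed$id, stringsAsFactors = FALSE)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn duptrp-io Read a BED file (3+ columns) into a data.frame with
#'   `chrom`, `start`, `end`, and `name`/`score` etc. when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- c(base, paste0("extra", seq_len(max(0, ncol(df) - 6))))[
    seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @describeIn duptrp-io Write a generic TSV table with header.
#' @param df any data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @describeIn duptrp-io Read a TSV table written by [write_tsv()].
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @describeIn duptrp-io Write one or more sequences to FASTA.
#' @param seqs named character vector of sequences, or a single character
#'   vector of bases (written as one record named `"chrSim"`).
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) && length(seqs) > 1L) {
    seqs <- paste(seqs, collapse = "")
    names(seqs) <- "chrSim"
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @describeIn duptrp-io Read a FASTA file into a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' Printed genomic intervals (`g.start-end`) are 1-based inclusive; internal
#' coordinates are 0-based half-open. `from_1based()` converts on input
#' (start - 1), `to_1based()` on output (start + 1).
#'
#' @param start,end interval bounds.
#' @return A list with `start` and `end` in the other convention.
#' @export
from_1based <- function(start, end) list(start = start - 1, end = end)

#' @rdname from_1based
#' @export
to_1based <- function(start, end) list(start = start + 1, end = end)
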