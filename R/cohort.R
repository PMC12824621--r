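#' Minimal region of overlap across triplicated intervals
#'
#' Intersection of all intervals (1-based inclusive, as printed in genomic
#' coordinates); returns the empty sentinel when the intervals are disjoint.
#' Order-invariant, associative, and monotonically shrinking as intervals
#' are added. Intervals flagged approximate propagate an `approximate`
#' attribute on the result.
#'
#' @param intervals data.frame with `start`, `end` (1-based inclusive) and
#'   optionally `approximate` (logical).
#' @return Named numeric `c(start, end)` or `NULL` when empty.
#' @examples
#' minimal_region_of_overlap(data.frame(start = c(2503226, 2495000),
#'                                      end = c(2540000, 2529370)))
#' @export
minimal_region_of_overlap <- function(intervals) {
  stopifnot(nrow(intervals) >= 1L)
  start <- max(intervals$start)
  end <- min(intervals$end)
  if (start > end) return(NULL)
  out <- c(start = start, end = end)
  if (!is.null(intervals$approximate) && any(intervals$approximate)) {
    attr(out, "approximate") <- TRUE
  }
  out
}

#' Length of a printed genomic interval in kilobases
#'
#' Printed intervals (`g.start-end`) are 1-based inclusive, so the length is
#' `(end - start + 1) / 1000`, rounded to `decimals`. (Inclusive and
#' exclusive arithmetic agree at the precisions such intervals are printed
#' with.)
#'
#' @param start,end interval bounds (1-based inclusive).
#' @param decimals decimal places of the returned value.
#' @param convention `"1based_inclusive"` (default) or `"0based_halfopen"`.
#' @return Length in kb.
#' @examples
#' interval_length_kb(2503226, 2529370, decimals = 1)  # 26.1
#' @export
interval_length_kb <- function(start, end, decimals = 1,
                               convention = c("1based_inclusive",
                                              "0based_halfopen")) {
  convention <- match.arg(convention)
  len <- switch(convention,
                "1based_inclusive" = end - start + 1,
                "0based_halfopen" = end - start)
  round(len / 1000, decimals)
}

#' Order statistics of per-individual SV sizes
#'
#' @param sizes numeric vector (>= 1 value), e.g. duplication or triplication
#'   sizes in kb.
#' @return Named numeric `c(min, max, median)` (exact order statistics).
#' @export
size_summary <- function(sizes) {
  stopifnot(length(sizes) >= 1L)
  c(min = min(sizes), max = max(sizes), median = stats::median(sizes))
}

#' Screen a population CNV call table against a target interval
#'
#' Keeps calls of length at least `min_size` that overlap the target by at
#' least one base pair, and classifies them by copy ratio: `DUP` within
#' `dup_band`, `TRIP` at or above `trip_threshold`, `AMBIGUOUS` otherwise.
#' The default bands place the constitutional expectations (1.5 for a
#' duplication, 2.0 for a triplication) centrally; classification is a
#' partition (every retained hit receives exactly one class).
#'
#' @param cnv data.frame with `sample`, `chrom`, `start`, `end`,
#'   `copy_ratio` (0-based half-open).
#' @param target_interval numeric `c(start, end)`, 0-based half-open, on
#'   `target_chrom`.
#' @param target_chrom chromosome of the target (default `"chr16"`).
#' @param min_size minimum call length in bp (default 10 kb).
#' @param dup_band copy-ratio interval `[low, high)` classified `DUP`.
#' @param trip_threshold copy ratio at or above which a call is `TRIP`.
#' @return list with `hits` (the retained calls plus a `class` column) and
#'   `class_counts` (named integer vector over DUP/TRIP/AMBIGUOUS).
#' @export
screen_population <- function(cnv, target_interval, target_chrom = "chr16",
                              min_size = 10000L,
                              dup_band = c(1.15, 1.75),
                              trip_threshold = 1.75) {
  if (min_size < 0) stop("min_size must be >= 0")
  req <- c("sample", "chrom", "start", "end", "copy_ratio")
  miss <- which(!stats::complete.cases(cnv[, intersect(req, names(cnv))]) |
                  cnv$end <= cnv$start)
  if (length(miss)) {
    warning("malformed CNV row(s) skipped: ",
            paste(utils::head(miss, 10L), collapse = ", "))
    cnv <- cnv[-miss, , drop = FALSE]
  }
  len <- cnv$end - cnv$start
  hit <- cnv$chrom == target_chrom & len >= min_size &
    cnv$start < target_interval[2] & cnv$end > target_interval[1]
  hits <- cnv[hit, , drop = FALSE]
  cls <- ifelse(hits$copy_ratio >= trip_threshold, "TRIP",
                ifelse(hits$copy_ratio >= dup_band[1] &
                         hits$copy_ratio < dup_band[2], "DUP", "AMBIGUOUS"))
  hits$class <- cls
  counts <- table(factor(cls, levels = c("DUP", "TRIP", "AMBIGUOUS")))
  list(hits = hits, class_counts = stats::setNames(as.integer(counts),
                                                   names(counts)))
}
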