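#' Normalize binned depth to copy ratios
#'
#' Converts per-bin counts to copy ratios `r = count / diploid_baseline`,
#' where the diploid baseline is the expected bin count at total copy number
#' 2 under the chosen strategy: the global median count, the median over
#' flank bins (the first and last `flank_frac` of bins, useful when the
#' centre of the locus is rearranged), or a caller-supplied value.
#'
#' Note that `global_median` is self-normalizing: doubling every count leaves
#' `r` unchanged, so it is only appropriate when most of the locus is diploid.
#'
#' @param bins depth bins (`chrom`, `start`, `end`, `count`).
#' @param baseline_strategy `"global_median"`, `"flank_median"` or
#'   `"fixed_value"`.
#' @param fixed_baseline diploid bin mean used with `"fixed_value"`.
#' @param flank_frac fraction of bins at each edge treated as flank.
#' @return The bins with columns `ratio` and attribute `diploid_baseline`.
#' @export
normalize_depth <- function(bins,
                            baseline_strategy = c("global_median",
                                                  "flank_median",
                                                  "fixed_value"),
                            fixed_baseline = NULL, flank_frac = 0.15) {
  baseline_strategy <- match.arg(baseline_strategy)
  if (nrow(bins) < 1L) stop("need at least one bin")
  baseline <- switch(baseline_strategy,
    global_median = stats::median(bins$count),
    flank_median = {
      k <- max(1L, floor(nrow(bins) * flank_frac))
      stats::median(c(utils::head(bins$count, k), utils::tail(bins$count, k)))
    },
    fixed_value = {
      if (is.null(fixed_baseline)) stop("fixed_value requires fixed_baseline")
      fixed_baseline
    })
  if (is.na(baseline) || baseline <= 0) stop("zero or invalid diploid baseline")
  bins$ratio <- bins$count / baseline
  attr(bins, "diploid_baseline") <- baseline
  bins
}

#' Segment copy ratios into integer total copy numbers
#'
#' Maximum a-posteriori state path over integer total copy numbers (default
#' 0..6) with per-bin Poisson emissions (mean `cn / 2 *` diploid bin mean) and
#' a uniform penalty per state change (Viterbi decoding). Ties break toward
#' the lower copy number. Runs of equal states are merged into segments;
#' segments shorter than `min_seg_bins` bins are absorbed into the neighbour
#' with the closer mean ratio, suppressing single-bin flickers such as those
#' produced by low-mapping-quality bins inside repeats.
#'
#' @param bins depth bins; if no `ratio` column is present they are first
#'   normalized with [normalize_depth()].
#' @param baseline_strategy,fixed_baseline passed to [normalize_depth()].
#' @param states integer copy-number states to consider.
#' @param transition_penalty positive penalty (natural log units) per state
#'   change; default `log(1e4)`.
#' @param min_seg_bins minimum segment length in bins (default 3).
#' @param mask optional BED data.frame; bins overlapping it contribute no
#'   emission term (e.g. zero-mappability bins).
#' @param refine_baseline if `TRUE` (default), after each decoding the
#'   diploid baseline is re-estimated from the assigned states
#'   (`2 * sum(count) / sum(cn)`, the Poisson MLE over all bins) and decoding
#'   is repeated until the path is stable (at most 5 rounds). This removes
#'   the bias of a baseline estimated from a handful of flank bins, which
#'   otherwise shifts step positions at the weakest (3 vs 4) contrasts.
#' @return A data.frame of segments with `chrom`, `start`, `end`, `cn`,
#'   `mean_ratio`, `n_bins`; adjacent segments always differ in `cn` and the
#'   union of segments equals the input span.
#' @examples
#' bins <- data.frame(chrom = "chrSim", start = 0:99 * 100,
#'                    end = 1:100 * 100,
#'                    count = c(rep(36, 40), rep(72, 20), rep(36, 40)))
#' segment_cn(bins, baseline_strategy = "flank_median")
#' @export
segment_cn <- function(bins, baseline_strategy = "flank_median",
                       fixed_baseline = NULL, states = 0:6,
                       transition_penalty = log(1e4), min_seg_bins = 3L,
                       mask = NULL, refine_baseline = TRUE) {
  if (nrow(bins) == 0L) stop("empty input")
  if (transition_penalty <= 0) stop("transition_penalty must be > 0")
  if (is.null(bins$ratio)) {
    bins <- normalize_depth(bins, baseline_strategy, fixed_baseline)
  }
  baseline <- attr(bins, "diploid_baseline")
  if (is.null(baseline)) baseline <- stats::median(bins$count / bins$ratio)
  masked <- rep(FALSE, nrow(bins))
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (i in seq_len(nrow(mask))) {
      masked <- masked | (bins$start < mask$end[i] & bins$end > mask$start[i])
    }
  }
  states <- sort(unique(as.integer(states)))
  cn <- NULL
  for (round in seq_len(if (refine_baseline) 5L else 1L)) {
    cn_new <- viterbi_cn(bins$count, masked, states, baseline,
                         transition_penalty)
    if (identical(cn_new, cn)) break
    cn <- cn_new
    if (refine_baseline && sum(cn[!masked]) > 0L) {
      baseline <- 2 * sum(bins$count[!masked]) / sum(cn[!masked])
    }
  }
  segs <- merge_cn_runs(bins, cn, baseline)
  absorb_short_segments(segs, bins, baseline, min_seg_bins)
}

viterbi_cn <- function(counts, masked, states, baseline, transition_penalty) {
  lam <- pmax(states, 0.05) / 2 * baseline
  n <- length(counts)
  S <- length(states)
  em <- vapply(seq_len(S), function(s) {
    e <- stats::dpois(counts, lam[s], log = TRUE)
    e[masked] <- 0
    e
  }, numeric(n))
  if (n == 1L) em <- matrix(em, nrow = 1L)
  # Viterbi; which.max on ascending states breaks ties toward lower CN
  score <- em[1, ]
  back <- matrix(NA_integer_, n, S)
  pen <- transition_penalty * (1 - diag(S))
  for (i in seq_len(n)[-1]) {
    cand <- matrix(score, S, S) - pen
    best <- apply(cand, 2, which.max)
    score <- cand[cbind(best, seq_len(S))] + em[i, ]
    back[i, ] <- best
  }
  path <- integer(n)
  path[n] <- which.max(score)
  if (n > 1L) {
    for (i in n:2) path[i - 1L] <- back[i, path[i]]
  }
  states[path]
}

merge_cn_runs <- function(bins, cn, baseline) {
  grp <- cumsum(c(TRUE, diff(cn) != 0))
  idx <- split(seq_along(cn), factor(grp, levels = unique(grp)))
  out <- lapply(idx, function(ii) {
    data.frame(chrom = bins$chrom[ii[1]],
               start = bins$start[ii[1]],
               end = bins$end[ii[length(ii)]],
               cn = cn[ii[1]],
               mean_ratio = mean(bins$count[ii]) / baseline,
               n_bins = length(ii), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

absorb_short_segments <- function(segs, bins, baseline, min_seg_bins) {
  repeat {
    short <- which(segs$n_bins < min_seg_bins)
    if (length(short) == 0L || nrow(segs) == 1L) break
    i <- short[which.min(segs$n_bins[short])]
    nbrs <- c(if (i > 1L) i - 1L, if (i < nrow(segs)) i + 1L)
    j <- nbrs[which.min(abs(segs$mean_ratio[nbrs] - segs$mean_ratio[i]))]
    segs$cn[i] <- segs$cn[j]
    # re-merge equal-cn runs
    cn_per_bin <- rep(segs$cn, segs$n_bins)
    segs <- merge_cn_runs(bins, cn_per_bin, baseline)
  }
  segs
}

#' Estimate the mosaic fraction from a segment copy ratio
#'
#' For a gain carried on one homolog with extra allele multiplicity `k`
#' (1 in a duplication-only region, 2 in a triplicated region) present in a
#' fraction `f` of cells, the expected copy ratio is `r = 1 + f * k / 2`, so
#' `f = 2 (r - 1) / k`. The 95% interval propagates the standard error of the
#' segment mean under Poisson bin counts. `f = 1` is the constitutional
#' state.
#'
#' @param r observed segment mean copy ratio.
#' @param k extra allele multiplicity on the rearranged homolog (1 or 2).
#' @param n_bins number of bins in the segment.
#' @param bin_mean diploid mean bin count (the baseline).
#' @return A list of class `mosaic_estimate`: `f`, `ci_low`, `ci_high`, `k`.
#' @examples
#' estimate_mosaic_fraction(r = 1.175, k = 1, n_bins = 1000, bin_mean = 36)
#' @export
estimate_mosaic_fraction <- function(r, k, n_bins, bin_mean) {
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  if (n_bins < 1L || bin_mean <= 0) stop("need n_bins >= 1 and bin_mean > 0")
  if (r < 1) {
    warning("copy ratio < 1 for an expected gain; clipping f to 0")
  }
  f_raw <- 2 * (r - 1) / k
  se_r <- sqrt(max(r, 0) / (bin_mean * n_bins))
  se_f <- 2 * se_r / k
  clip <- function(x) min(1, max(0, x))
  out <- list(f = clip(f_raw),
              ci_low = clip(f_raw - 1.96 * se_f),
              ci_high = clip(f_raw + 1.96 * se_f),
              k = as.integer(k))
  class(out) <- "mosaic_estimate"
  out
}

#' @export
print.mosaic_estimate <- function(x, ...) {
  cat(sprintf("mosaic fraction f = %.3f (95%% CI %.3f-%.3f, k = %d)\n",
              x$f, x$ci_low, x$ci_high, x$k))
  invisible(x)
}
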