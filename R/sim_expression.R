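#' Simulate an expression cohort with a dosage effect in one index sample
#'
#' Control samples are log-normal around per-gene baselines with coefficient
#' of variation `cv`; the index sample's target gene is scaled by `dosage_fc`
#' (under the naive proportional dosage model a constitutional triplication,
#' total CN 4, gives `dosage_fc = 2`). Housekeeping genes are never scaled.
#'
#' @param cohort_n number of control samples (the index sample is added on
#'   top, as `"INDEX"`).
#' @param dosage_fc fold-change planted on `target_gene` in the index sample.
#' @param cv coefficient of variation of expression noise.
#' @param seed integer seed.
#' @param genes named numeric vector of baseline TPM values; defaults to a
#'   small panel around the triplicated locus plus two housekeeping genes.
#' @param target_gene,hk_genes gene identifiers within `genes`.
#' @return A list with `tpm` (genes x samples matrix), `index_sample`,
#'   `target_gene`, `hk_genes`.
#' @examples
#' sim <- simulate_expression(cohort_n = 20, dosage_fc = 2, cv = 0.1, seed = 1)
#' dim(sim$tpm)
#' @export
simulate_expression <- function(cohort_n, dosage_fc, cv, seed,
                                genes = c(ATP6V0C = 120, AMDHD2 = 35,
                                          TBC1D24 = 18, PDPK1 = 40,
                                          NEIGHBOR1 = 25, GAPDH = 1500,
                                          ACTB = 2000),
                                target_gene = "ATP6V0C",
                                hk_genes = c("GAPDH", "ACTB")) {
  stopifnot(cohort_n >= 1, dosage_fc > 0, cv >= 0,
            target_gene %in% names(genes), all(hk_genes %in% names(genes)))
  set.seed(seed + 3L)
  samples <- c(sprintf("CTRL%03d", seq_len(cohort_n)), "INDEX")
  sdlog <- sqrt(log(1 + cv^2))
  # meanlog chosen so the expectation equals the baseline
  tpm <- sapply(samples, function(s) {
    stats::rlnorm(length(genes), meanlog = log(genes) - sdlog^2 / 2,
                  sdlog = sdlog)
  })
  rownames(tpm) <- names(genes)
  tpm[target_gene, "INDEX"] <- tpm[target_gene, "INDEX"] * dosage_fc
  list(tpm = tpm, index_sample = "INDEX", target_gene = target_gene,
       hk_genes = hk_genes)
}

#' Simulate a population CNV call table around a target interval
#'
#' Plants `n_dup` duplication calls overlapping `target_interval` (truth-driven
#' planting, not per-sample Bernoulli) with copy ratios drawn around the
#' constitutional duplication expectation of 1.5, plus `n_background`
#' calls elsewhere on the chromosome. No triplications are planted unless
#' `n_trip > 0`.
#'
#' @param n_samples nominal cohort size (sample ids are drawn from it).
#' @param n_dup number of duplications overlapping the target.
#' @param n_trip number of triplications overlapping the target (default 0).
#' @param target_interval numeric `c(start, end)`, 0-based half-open.
#' @param size_range duplication length range (bp), log-uniform.
#' @param ratio_sd spread of simulated copy ratios around their expectation.
#' @param n_background calls not overlapping the target.
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @return A data.frame with `sample`, `chrom`, `start`, `end`, `copy_ratio`.
#' @export
simulate_population_cnv <- function(n_samples, n_dup, target_interval,
                                    n_trip = 0L,
                                    size_range = c(25000, 3e6),
                                    ratio_sd = 0.07,
                                    n_background = 50L,
                                    chrom = "chr16", seed = 1L) {
  stopifnot(length(target_interval) == 2L,
            target_interval[1] < target_interval[2])
  set.seed(seed + 4L)
  tw <- target_interval[2] - target_interval[1]
  mk <- function(n, ratio_mu, overlap) {
    if (n == 0L) {
      return(data.frame(sample = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        copy_ratio = numeric(0), stringsAsFactors = FALSE))
    }
    len <- round(exp(stats::runif(n, log(size_range[1]), log(size_range[2]))))
    if (overlap) {
      # anchor each call so that it overlaps the target by >= 1 bp
      start <- round(stats::runif(n, target_interval[1] - len + 1,
                                  target_interval[2] - 1))
    } else {
      start <- round(stats::runif(n, target_interval[2] + 1e6,
                                  target_interval[2] + 5e7))
    }
    ratio <- pmax(1.05, stats::rnorm(n, ratio_mu, ratio_sd))
    data.frame(sample = sprintf("UKB%06d", sample.int(n_samples, n)),
               chrom = chrom, start = as.integer(start),
               end = as.integer(start + len),
               copy_ratio = round(ratio, 3), stringsAsFactors = FALSE)
  }
  out <- rbind(mk(n_dup, 1.5, TRUE), mk(n_trip, 2.0, TRUE),
               mk(n_background, 1.5, FALSE))
  out[order(out$start), , drop = FALSE]
}
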