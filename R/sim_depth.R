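#' Simulate binned read depth from a truth copy-number profile
#'
#' Bins tile the locus; each bin's count is drawn independently with mean
#' `haploid_depth * (2 + f * (T - 2))`, where `T` is the constitutional total
#' copy number of the bin and `f` the mosaic fraction (the intact homolog
#' contributes one haploid copy in every cell; `f = 1` gives the
#' constitutional state). Noise is Poisson by default, or negative binomial
#' with dispersion `nb_dispersion`.
#'
#' @param truth a `duptrp_truth` object (or any list with
#'   `truth_cn_profile` and `config`).
#' @param f mosaic fraction override; defaults to `config$mosaic_fraction`.
#' @param seed seed override; defaults to `config$seed`.
#' @return A bedGraph-like data.frame with columns `chrom`, `start`, `end`,
#'   `count` (0-based half-open bins, sorted, non-overlapping).
#' @examples
#' ref <- build_reference(sim_config(seed = 1, flank_len = 2000,
#'   dup_left_len = 800, trp_len = 1200, dup_right_len = 800,
#'   palindrome_arm_len = 600, palindrome_spacer_len = 200,
#'   cis_morphism_offsets = c(150, 450), bin_size = 100))
#' bins <- simulate_depth(apply_architecture(ref))
#' head(bins)
#' @export
simulate_depth <- function(truth, f = NULL, seed = NULL) {
  cfg <- truth$config
  f <- f %||% cfg$mosaic_fraction
  seed <- seed %||% cfg$seed
  cnp <- truth$truth_cn_profile
  L <- max(cnp$end)
  bs <- cfg$bin_size
  if (bs > min(cnp$end - cnp$start)) {
    warning("bin_size (", bs, ") exceeds the smallest truth segment; ",
            "step positions will be quantised coarsely")
  }
  starts <- seq(0L, L - 1L, by = bs)
  ends <- pmin(starts + bs, L)
  if (length(starts) == 0L) stop("zero bins: locus shorter than one bin")
  mid <- (starts + ends) / 2
  idx <- findInterval(mid, cnp$start)
  T_cn <- cnp$cn[idx]
  mu <- cfg$haploid_depth * (2 + f * (T_cn - 2)) * (ends - starts) / bs
  set.seed(seed)
  count <- if (cfg$depth_noise == "nb") {
    stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  data.frame(chrom = cnp$chrom[1], start = as.integer(starts),
             end = as.integer(ends), count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Simulate junction-supporting read-pair evidence (BEDPE rows)
#'
#' Each truth junction emits `n_junction_pairs` BEDPE rows carrying the
#' junction's strand pair, with both breakend positions jittered independently
#' and uniformly within `position_jitter` bp.
#'
#' @param truth a `duptrp_truth` object.
#' @param n_pairs,jitter,seed overrides for `n_junction_pairs`,
#'   `position_jitter` and `seed` from the configuration.
#' @return A BEDPE data.frame with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `name`, `score`, `strand1`, `strand2`
#'   (empty for the reference architecture).
#' @export
simulate_junction_evidence <- function(truth, n_pairs = NULL, jitter = NULL,
                                       seed = NULL) {
  cfg <- truth$config
  n_pairs <- n_pairs %||% cfg$n_junction_pairs
  jitter <- jitter %||% cfg$position_jitter
  seed <- seed %||% cfg$seed
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  jx <- truth$truth_junctions
  set.seed(seed + 1L)
  rows <- lapply(seq_len(nrow(jx)), function(i) {
    j1 <- if (jitter > 0) sample(-jitter:jitter, n_pairs, TRUE) else 0L
    j2 <- if (jitter > 0) sample(-jitter:jitter, n_pairs, TRUE) else 0L
    p1 <- pmax(0L, jx$pos1[i] + j1)
    p2 <- pmax(0L, jx$pos2[i] + j2)
    data.frame(chrom1 = jx$chrom1[i], start1 = as.integer(p1),
               end1 = as.integer(p1 + 1L),
               chrom2 = jx$chrom2[i], start2 = as.integer(p2),
               end2 = as.integer(p2 + 1L),
               name = sprintf("jx%d_pair%d", i, seq_len(n_pairs)),
               score = 60L,
               strand1 = jx$strand1[i], strand2 = jx$strand2[i],
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      name = character(0), score = integer(0),
                      strand1 = character(0), strand2 = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
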