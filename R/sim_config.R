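#' Simulation configuration for the DUP-TRP/INV-DUP evidence generator
#'
#' Bundles the geometry of the simulated locus, the planted rearrangement and
#' the noise model into a validated configuration object. All coordinates are
#' 0-based, half-open; all lengths are in base pairs.
#'
#' The simulated reference is laid out left (proximal) to right (distal) as
#' `flank_left | palindrome_arm_1 | spacer | palindrome_arm_2 | dup_left |
#' trp | dup_right | flank_right`. The two palindrome arms are reverse
#' complements of each other up to `arm_identity`, and carry two
#' paralog-distinguishing cis-morphism sites at `cis_morphism_offsets`
#' (arm-1 coordinates; default separation 4,200 bp).
#'
#' @param seed integer seed controlling every random choice downstream.
#' @param flank_len,dup_left_len,trp_len,dup_right_len segment lengths (bp).
#' @param palindrome_arm_len,palindrome_spacer_len inverted-repeat geometry (bp).
#' @param arm_identity fraction in (0, 1]; sequence identity between arm 2 and
#'   the reverse complement of arm 1 (cis-morphism sites excluded).
#' @param cis_morphism_offsets two arm-1 offsets (bp, strictly inside the arm)
#'   of the paralog-distinguishing sites, or `NULL` for none.
#' @param architecture_id one of `"REF"`, `"TANDEM_DUP"`, `"DUPTRP_1"` ..
#'   `"DUPTRP_4"`, `"DEL_INV"`.
#' @param mosaic_fraction fraction `f` in \[0, 1\] of cells carrying the
#'   rearranged allele; 1 is the constitutional state.
#' @param haploid_depth mean read count per bin per haploid copy.
#' @param bin_size depth bin width (bp).
#' @param n_junction_pairs split/discordant read pairs emitted per true junction.
#' @param position_jitter half-width (bp) of the uniform jitter applied to
#'   emitted junction breakend positions.
#' @param long_read_len_mean,n_long_reads long-read length model (mean bp; the
#'   standard deviation is 10% of the mean) and read count.
#' @param expression_cohort_n control cohort size for the expression simulator.
#' @param dosage_fc fold-change planted on the target gene in the index sample.
#' @param expression_cv coefficient of variation of control expression values.
#' @param proximal_in_palindrome logical; if `TRUE` the proximal breakpoints of
#'   DUP-TRP architectures are placed at paralogous positions inside the two
#'   palindrome arms, midway between the cis-morphism sites (the
#'   palindrome-mediated physical model, required for cis-morphism phasing).
#'   If `FALSE` (default) they sit at the `dup_left`/`trp` segment boundaries
#'   so that the named segments carry total copy numbers (3, 4, 3) exactly.
#' @param depth_noise `"poisson"` (default) or `"nb"`.
#' @param nb_dispersion negative-binomial size parameter used when
#'   `depth_noise = "nb"` (smaller = more overdispersed).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$trp_len
#' @export
sim_config <- function(seed = 1L,
                       flank_len = 50000L,
                       dup_left_len = 30000L,
                       trp_len = 40000L,
                       dup_right_len = 30000L,
                       palindrome_arm_len = 20000L,
                       palindrome_spacer_len = 4000L,
                       arm_identity = 0.998,
                       cis_morphism_offsets = c(7900L, 12100L),
                       architecture_id = "DUPTRP_1",
                       mosaic_fraction = 1,
                       haploid_depth = 18,
                       bin_size = 500L,
                       n_junction_pairs = 20L,
                       position_jitter = 50L,
                       long_read_len_mean = 20000L,
                       n_long_reads = 800L,
                       expression_cohort_n = 100L,
                       dosage_fc = 2,
                       expression_cv = 0.1,
                       proximal_in_palindrome = FALSE,
                       depth_noise = c("poisson", "nb"),
                       nb_dispersion = 20) {
  depth_noise <- match.arg(depth_noise)
  lens <- c(flank_len = flank_len, dup_left_len = dup_left_len,
            trp_len = trp_len, dup_right_len = dup_right_len,
            palindrome_arm_len = palindrome_arm_len,
            palindrome_spacer_len = palindrome_spacer_len)
  if (any(lens <= 0)) {
    stop("all segment lengths must be > 0; offending: ",
         paste(names(lens)[lens <= 0], collapse = ", "))
  }
  if (mosaic_fraction < 0 || mosaic_fraction > 1) {
    stop("mosaic_fraction must lie in [0, 1]")
  }
  if (arm_identity <= 0 || arm_identity > 1) {
    stop("arm_identity must lie in (0, 1]")
  }
  if (!is.null(cis_morphism_offsets)) {
    if (length(cis_morphism_offsets) != 2L) {
      stop("cis_morphism_offsets must contain exactly two offsets (or be NULL)")
    }
    cis_morphism_offsets <- sort(as.integer(cis_morphism_offsets))
    if (cis_morphism_offsets[1] <= 0L ||
        cis_morphism_offsets[2] >= palindrome_arm_len - 1L) {
      stop("cis_morphism_offsets must be strictly inside the arm")
    }
  }
  n_div <- round((1 - arm_identity) * palindrome_arm_len)
  if (n_div > palindrome_arm_len - length(cis_morphism_offsets) * 2L) {
    stop("arm_identity incompatible with arm length: ", n_div,
         " divergent positions do not fit")
  }
  if (!architecture_id %in% duptrp_architectures()) {
    stop("unknown architecture_id: ", architecture_id)
  }
  if (haploid_depth <= 0) stop("haploid_depth must be > 0")
  cfg <- list(seed = as.integer(seed),
              flank_len = as.integer(flank_len),
              dup_left_len = as.integer(dup_left_len),
              trp_len = as.integer(trp_len),
              dup_right_len = as.integer(dup_right_len),
              palindrome_arm_len = as.integer(palindrome_arm_len),
              palindrome_spacer_len = as.integer(palindrome_spacer_len),
              arm_identity = arm_identity,
              cis_morphism_offsets = cis_morphism_offsets,
              architecture_id = architecture_id,
              mosaic_fraction = mosaic_fraction,
              haploid_depth = haploid_depth,
              bin_size = as.integer(bin_size),
              n_junction_pairs = as.integer(n_junction_pairs),
              position_jitter = as.integer(position_jitter),
              long_read_len_mean = as.integer(long_read_len_mean),
              n_long_reads = as.integer(n_long_reads),
              expression_cohort_n = as.integer(expression_cohort_n),
              dosage_fc = dosage_fc,
              expression_cv = expression_cv,
              proximal_in_palindrome = isTRUE(proximal_in_palindrome),
              depth_noise = depth_noise,
              nb_dispersion = nb_dispersion)
  class(cfg) <- "sim_config"
  cfg
}

#' Valid architecture identifiers
#'
#' @return Character vector of the rearrangement architectures the simulator
#'   can plant: the reference allele, a simple tandem duplication, the four
#'   inverted duplication-triplication configurations that explain the same
#'   short-read evidence, and a deletion-inversion.
#' @export
duptrp_architectures <- function() {
  c("REF", "TANDEM_DUP", paste0("DUPTRP_", 1:4), "DEL_INV")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$architecture_id,
      sprintf("(f = %.2f, haploid depth %.1f, bin %d bp)\n",
              x$mosaic_fraction, x$haploid_depth, x$bin_size))
  cat(sprintf("  locus: flank %d | arm %d | spacer %d | arm %d | dup %d | trp %d | dup %d | flank %d\n",
              x$flank_len, x$palindrome_arm_len, x$palindrome_spacer_len,
              x$palindrome_arm_len, x$dup_left_len, x$trp_len,
              x$dup_right_len, x$flank_len))
  invisible(x)
}
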