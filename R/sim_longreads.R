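#' Simulate long reads and cis-morphism allele observations
#'
#' Samples reads from the two haplotypes of the simulated individual (the
#' intact reference homolog and the rearranged allele) in proportion to
#' molecule length, and reports, for every read, the allele observed at each
#' cis-morphism site it covers. Observations are expressed in the arm-1
#' forward frame, so a read through arm 1 reports `arm1_allele` at both sites,
#' a read through arm 2 reports `arm2_allele`, and a read crossing a proximal
#' junction planted between the sites reports a chimeric pattern (one allele
#' from each arm) -- the signal used by [phase_breakpoint()].
#'
#' Both paralogous copies of a site yield observations: an aligner cannot
#' distinguish them within a near-identical repeat, so the site identity, not
#' the arm, is the observation key.
#'
#' @param ref a [build_reference()] object.
#' @param truth a `duptrp_truth` from [apply_architecture()].
#' @param n,len_mean,seed overrides for `n_long_reads`, `long_read_len_mean`
#'   and `seed`.
#' @param error_rate per-site observation error rate (default 0.01); an
#'   erroneous observation is a uniformly chosen different base.
#' @param return_sequences if `TRUE`, attach the read sequences (named
#'   character vector) for FASTA export.
#' @return A list with `reads` (read_id, molecule, start, length),
#'   `observations` (read_id, site_id, allele), and optionally `sequences`.
#' @export
simulate_long_reads <- function(ref, truth, n = NULL, len_mean = NULL,
                                seed = NULL, error_rate = 0.01,
                                return_sequences = FALSE) {
  cfg <- ref$config
  n <- n %||% cfg$n_long_reads
  len_mean <- len_mean %||% cfg$long_read_len_mean
  seed <- seed %||% cfg$seed
  sites <- ref$sites
  if (!is.null(sites) && nrow(sites) == 2L) {
    span <- abs(sites$arm_offset[2] - sites$arm_offset[1])
    if (len_mean < span) {
      warning("long_read_len_mean (", len_mean, ") is shorter than the ",
              "inter-site distance (", span, "); phasing will be impossible")
    }
  }
  empty_obs <- data.frame(read_id = character(0), site_id = character(0),
                          allele = character(0), stringsAsFactors = FALSE)
  empty_reads <- data.frame(read_id = character(0), molecule = character(0),
                            start = integer(0), length = integer(0),
                            stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(reads = empty_reads, observations = empty_obs))
  }

  molecules <- list(
    normal = list(runs = list(list(start = 0L, end = length(ref$seq),
                                   orient = "+")),
                  len = length(ref$seq)),
    rearranged = list(runs = truth$runs, len = length(truth$haplotype))
  )

  # site occurrences in molecule coordinates
  occ_for <- function(runs) {
    if (is.null(sites)) return(NULL)
    out <- list()
    mstart <- 0L
    for (r in runs) {
      rl <- r$end - r$start
      for (i in seq_len(nrow(sites))) {
        for (col in c("arm1_pos", "arm2_pos")) {
          pos <- sites[[col]][i]
          if (pos >= r$start && pos < r$end) {
            mpos <- if (r$orient == "+") mstart + (pos - r$start)
                    else mstart + (r$end - 1L - pos)
            allele <- if (col == "arm1_pos") sites$arm1_allele[i]
                      else sites$arm2_allele[i]
            out[[length(out) + 1L]] <- data.frame(
              mpos = mpos, site_id = sites$site_id[i], allele = allele,
              stringsAsFactors = FALSE)
          }
        }
      }
      mstart <- mstart + rl
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  occs <- lapply(molecules, function(m) occ_for(m$runs))

  set.seed(seed + 2L)
  lens <- vapply(molecules, function(m) m$len, numeric(1))
  mol_pick <- sample(names(molecules), n, replace = TRUE,
                     prob = lens / sum(lens))
  read_len <- pmax(500L, as.integer(round(stats::rnorm(n, len_mean,
                                                       0.1 * len_mean))))
  read_len <- pmin(read_len, as.integer(lens[mol_pick]))
  start <- vapply(seq_len(n), function(i) {
    as.integer(floor(stats::runif(1, 0, lens[mol_pick[i]] - read_len[i] + 1)))
  }, integer(1))
  reads <- data.frame(read_id = sprintf("read%05d", seq_len(n)),
                      molecule = mol_pick, start = start, length = read_len,
                      stringsAsFactors = FALSE)

  obs <- empty_obs
  if (!is.null(sites)) {
    rows <- list()
    for (i in seq_len(n)) {
      oc <- occs[[mol_pick[i]]]
      if (is.null(oc)) next
      hit <- oc$mpos >= start[i] & oc$mpos < start[i] + read_len[i]
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = reads$read_id[i], site_id = oc$site_id[hit],
          allele = oc$allele[hit], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) obs <- do.call(rbind, rows)
    if (nrow(obs) && error_rate > 0) {
      err <- stats::runif(nrow(obs)) < error_rate
      if (any(err)) {
        obs$allele[err] <- vapply(obs$allele[err], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1))
      }
    }
  }
  rownames(obs) <- NULL

  out <- list(reads = reads, observations = obs)
  if (return_sequences) {
    seqs <- list(normal = paste(ref$seq, collapse = ""),
                 rearranged = paste(truth$haplotype, collapse = ""))
    out$sequences <- vapply(seq_len(n), function(i) {
      substr(seqs[[mol_pick[i]]], start[i] + 1L, start[i] + read_len[i])
    }, character(1))
    names(out$sequences) <- reads$read_id
  }
  out
}
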