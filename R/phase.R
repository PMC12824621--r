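#' Phase a proximal breakpoint from cis-morphism allele observations
#'
#' Reads spanning both paralog-distinguishing sites of an inverted-repeat
#' pair are informative: a read through an intact arm observes the same arm's
#' allele at both sites, while a read crossing a junction that falls between
#' the sites observes a chimeric pattern (one allele from each arm). If a
#' chimeric pattern is supported by at least `min_informative_reads` reads
#' and accounts for at least `confidence_threshold` of all chimeric-pattern
#' reads (the subset of informative reads that can only derive from the
#' rearranged haplotype), the breakpoint is localized to the open interval
#' between the two site positions.
#'
#' Observations with a base matching neither arm allele are ignored as
#' sequencing error; reads observing a site more than once with conflicting
#' alleles (possible only for reads spanning most of the repeat) are dropped
#' as ambiguous.
#'
#' @param observations data.frame with `read_id`, `site_id`, `allele` (from
#'   [simulate_long_reads()] or [read_tsv()]).
#' @param sites cis-morphism site table (`site_id`, `arm1_pos`, `arm2_pos`,
#'   `arm1_allele`, `arm2_allele`), two sites.
#' @param min_informative_reads minimum chimeric support for a call
#'   (default 5; a case supported by only four reads is deliberately below
#'   this threshold).
#' @param confidence_threshold minimum fraction of chimeric-pattern reads
#'   agreeing on the dominant pattern (default 0.8).
#' @return A list of class `phasing_result`: `pattern_counts` (named:
#'   `arm1_arm1`, `arm1_arm2`, `arm2_arm1`, `arm2_arm2`),
#'   `n_informative`, `breakpoint_interval` (`c(start, end)` in arm-1
#'   coordinates, or `NULL` for no call), `confidence`, `called`, `reason`.
#' @export
phase_breakpoint <- function(observations, sites,
                             min_informative_reads = 5L,
                             confidence_threshold = 0.8) {
  stopifnot(nrow(sites) == 2L)
  sites <- sites[order(sites$arm1_pos), ]
  s1 <- sites[1, ]; s2 <- sites[2, ]
  no_call <- function(reason, counts, n_inf, conf = NA_real_) {
    structure(list(pattern_counts = counts, n_informative = n_inf,
                   breakpoint_interval = NULL, confidence = conf,
                   called = FALSE, reason = reason),
              class = "phasing_result")
  }
  counts <- c(arm1_arm1 = 0L, arm1_arm2 = 0L, arm2_arm1 = 0L, arm2_arm2 = 0L)

  if (nrow(observations) == 0L) {
    return(no_call("no observations", counts, 0L))
  }
  lab <- function(site, allele) {
    ifelse(allele == site$arm1_allele, "arm1",
           ifelse(allele == site$arm2_allele, "arm2", NA_character_))
  }
  obs <- observations
  obs$arm <- NA_character_
  for (sid in sites$site_id) {
    sel <- obs$site_id == sid
    obs$arm[sel] <- lab(sites[sites$site_id == sid, ], obs$allele[sel])
  }
  obs <- obs[!is.na(obs$arm), , drop = FALSE]

  # per read x site: drop reads with conflicting duplicate observations
  key <- paste(obs$read_id, obs$site_id)
  n_alleles <- tapply(obs$arm, key, function(a) length(unique(a)))
  bad_reads <- unique(obs$read_id[key %in% names(n_alleles)[n_alleles > 1]])
  obs <- obs[!obs$read_id %in% bad_reads & !duplicated(key), , drop = FALSE]

  a1 <- obs$arm[obs$site_id == s1$site_id]
  names(a1) <- obs$read_id[obs$site_id == s1$site_id]
  a2 <- obs$arm[obs$site_id == s2$site_id]
  names(a2) <- obs$read_id[obs$site_id == s2$site_id]
  both <- intersect(names(a1), names(a2))
  n_inf <- length(both)
  if (n_inf > 0L) {
    pat <- paste(a1[both], a2[both], sep = "_")
    tb <- table(factor(pat, levels = names(counts)))
    counts[names(tb)] <- as.integer(tb)
  }
  chim <- counts[c("arm1_arm2", "arm2_arm1")]
  if (max(chim) < min_informative_reads) {
    return(no_call(sprintf(
      "chimeric support %d below min_informative_reads = %d",
      max(chim), min_informative_reads), counts, n_inf))
  }
  conf <- max(chim) / sum(chim)
  if (conf < confidence_threshold) {
    return(no_call(sprintf("chimera confidence %.2f below threshold %.2f",
                           conf, confidence_threshold), counts, n_inf, conf))
  }
  structure(list(pattern_counts = counts, n_informative = n_inf,
                 breakpoint_interval = c(start = s1$arm1_pos,
                                         end = s2$arm1_pos),
                 confidence = conf, called = TRUE, reason = "chimera"),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("phasing_result:", if (x$called) sprintf(
    "breakpoint in (%d, %d), confidence %.2f",
    x$breakpoint_interval["start"], x$breakpoint_interval["end"],
    x$confidence) else paste("no call --", x$reason), "\n")
  cat("  patterns:", paste(names(x$pattern_counts), x$pattern_counts,
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a phasing result to JSON
#' @param x a `phasing_result`.
#' @param path output file.
#' @export
write_phasing_json <- function(x, path) {
  jsonlite::write_json(list(
    pattern_counts = as.list(x$pattern_counts),
    n_informative = x$n_informative,
    called = x$called,
    confidence = x$confidence,
    breakpoint_interval = if (is.null(x$breakpoint_interval)) NULL else
      as.list(x$breakpoint_interval),
    reason = x$reason), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
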