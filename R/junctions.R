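JUNCTION_CLASSES <- c("DEL_LIKE", "TANDEM_DUP_LIKE", "INV_HEAD_HEAD",
                      "INV_TAIL_TAIL", "INTERCHROM")

#' Classify a breakpoint junction from its strand pair
#'
#' With breakends ordered `a <= b` on the same chromosome, the read-pair
#' strand convention maps to junction classes as: `(+,+)` head-to-head
#' inversion, `(-,-)` tail-to-tail inversion (the distal junction of an
#' inverted duplication-triplication, whose supporting read pairs both map to
#' the negative strand), `(+,-)` deletion-like, `(-,+)` tandem-duplication-
#' like. Breakends on different chromosomes are `INTERCHROM`.
#'
#' @param strand1,strand2 strands (`"+"` or `"-"`) of the ordered breakends.
#' @param chrom1,chrom2 chromosomes of the two breakends.
#' @return One of `r paste(JUNCTION_CLASSES, collapse = ", ")`.
#' @examples
#' classify_junction("-", "-")  # INV_TAIL_TAIL
#' @export
classify_junction <- function(strand1, strand2,
                              chrom1 = "chrSim", chrom2 = chrom1) {
  if (!all(c(strand1, strand2) %in% c("+", "-"))) {
    stop("invalid strand symbol: ", strand1, "/", strand2)
  }
  if (chrom1 != chrom2) return("INTERCHROM")
  key <- paste0(strand1, strand2)
  switch(key,
         "++" = "INV_HEAD_HEAD",
         "--" = "INV_TAIL_TAIL",
         "+-" = "DEL_LIKE",
         "-+" = "TANDEM_DUP_LIKE")
}

#' Cluster junction-supporting BEDPE rows into junction calls
#'
#' Rows sharing a strand pair whose breakends lie within
#' `max_cluster_distance` of a cluster member merge into one call positioned
#' at the median breakend positions; calls supported by fewer than
#' `min_support` rows are dropped. Clustering is permutation-invariant (rows
#' are canonically sorted first) and idempotent.
#'
#' @param bedpe BEDPE data.frame (see [read_bedpe()]); breakends are taken to
#'   be at `start1`/`start2` and are reordered so that breakend a <= b.
#' @param max_cluster_distance maximum breakend distance (bp) for two rows to
#'   join the same cluster; default 500.
#' @param min_support minimum supporting rows per call; default 3.
#' @return A data.frame of junction calls: `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`, `support`, `jclass`.
#' @examples
#' jx <- data.frame(chrom1 = "c", start1 = c(100, 120), end1 = c(101, 121),
#'                  chrom2 = "c", start2 = c(900, 880), end2 = c(901, 881),
#'                  name = c("a", "b"), score = 60,
#'                  strand1 = "-", strand2 = "-")
#' cluster_junctions(jx, min_support = 2)
#' @export
cluster_junctions <- function(bedpe, max_cluster_distance = 500L,
                              min_support = 3L) {
  if (max_cluster_distance < 0) stop("max_cluster_distance must be >= 0")
  empty <- data.frame(chrom1 = character(0), pos1 = integer(0),
                      strand1 = character(0), chrom2 = character(0),
                      pos2 = integer(0), strand2 = character(0),
                      support = integer(0), jclass = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(bedpe) == 0L) return(empty)
  df <- data.frame(chrom1 = bedpe$chrom1, pos1 = bedpe$start1,
                   strand1 = bedpe$strand1,
                   chrom2 = bedpe$chrom2, pos2 = bedpe$start2,
                   strand2 = bedpe$strand2, stringsAsFactors = FALSE)
  # canonical breakend order a <= b
  flip <- (df$chrom1 > df$chrom2) |
    (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
  df[flip, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
    df[flip, c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1")]
  df <- df[order(df$chrom1, df$chrom2, df$strand1, df$strand2,
                 df$pos1, df$pos2), , drop = FALSE]

  key <- paste(df$chrom1, df$chrom2, df$strand1, df$strand2)
  calls <- list()
  for (grp in split(df, key)) {
    # single-linkage chaining along pos1/pos2 within the strand-pair group
    n <- nrow(grp)
    newc <- c(TRUE, (diff(grp$pos1) > max_cluster_distance) |
                    (abs(diff(grp$pos2)) > max_cluster_distance))
    cl <- cumsum(newc)
    for (sub in split(grp, cl)) {
      calls[[length(calls) + 1L]] <- data.frame(
        chrom1 = sub$chrom1[1],
        pos1 = as.integer(round(stats::median(sub$pos1))),
        strand1 = sub$strand1[1],
        chrom2 = sub$chrom2[1],
        pos2 = as.integer(round(stats::median(sub$pos2))),
        strand2 = sub$strand2[1],
        support = nrow(sub),
        jclass = classify_junction(sub$strand1[1], sub$strand2[1],
                                   sub$chrom1[1], sub$chrom2[1]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, calls)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chrom1, out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) empty else out
}
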