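#' Detect inverted repeats (palindrome-like arm pairs) in a sequence
#'
#' Seed-and-extend detection: exact k-mer matches between the sequence and
#' its reverse complement are chained along anti-diagonals and extended
#' base-by-base while the arm-pair mismatch fraction stays within
#' `max_mismatch_fraction`; maximal non-overlapping arm pairs with separation
#' at most `max_spacer` are reported. Suited to desk-scale sequences
#' (< 1 Mb); no suffix-tree machinery.
#'
#' @param seq character vector of bases, a single string, or a
#'   `duptrp_reference`.
#' @param min_arm minimum arm length (bp, >= 8).
#' @param max_spacer maximum separation between the arms (bp).
#' @param max_mismatch_fraction maximum fraction of mismatching positions
#'   between arm 2 and the reverse complement of arm 1.
#' @param seed_k seed k-mer length (default 16, reduced to `min_arm` if
#'   smaller).
#' @return data.frame with `arm1_start`, `arm1_end`, `arm2_start`,
#'   `arm2_end`, `spacer_len`, `arm_len`, `identity` (0-based half-open,
#'   sorted, non-overlapping). Empty when the sequence is shorter than
#'   `2 * min_arm`.
#' @examples
#' set.seed(1)
#' arm <- sample(c("A", "C", "G", "T"), 600, TRUE)
#' s <- c(sample(c("A", "C", "G", "T"), 400, TRUE), arm, rev(chartr("ACGT",
#'   "TGCA", arm)), sample(c("A", "C", "G", "T"), 400, TRUE))
#' find_inverted_repeats(s, min_arm = 100, max_spacer = 100)
#' @export
find_inverted_repeats <- function(seq, min_arm = 1000L, max_spacer = 50000L,
                                  max_mismatch_fraction = 0.02,
                                  seed_k = 16L) {
  if (inherits(seq, "duptrp_reference")) seq <- seq$seq
  if (length(seq) == 1L && nchar(seq[1]) > 1L) {
    seq <- strsplit(seq, "")[[1]]
  }
  if (min_arm < 8L) stop("min_arm must be >= 8")
  n <- length(seq)
  empty <- data.frame(arm1_start = integer(0), arm1_end = integer(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      spacer_len = integer(0), arm_len = integer(0),
                      identity = numeric(0))
  if (n < 2L * min_arm) return(empty)
  k <- min(seed_k, min_arm)
  s <- paste(seq, collapse = "")
  comp <- chartr("ACGT", "TGCA", seq)

  # seeds: forward k-mer at i (0-based) matching revcomp k-mer whose original
  # window starts at b (0-based): seq[b..b+k) == revcomp(seq[i..i+k))
  fk <- substring(s, 1:(n - k + 1L), k:n)
  rs <- paste(rev(comp), collapse = "")
  rk <- substring(rs, 1:(n - k + 1L), k:n)
  # rk[q] (1-based q) corresponds to original window starting at b0 = n-q-k+1
  common <- intersect(fk, rk)
  if (length(common) == 0L) return(empty)
  # drop hyper-abundant seeds (low-complexity guard)
  tab_f <- table(fk[fk %in% common])
  common <- names(tab_f)[tab_f <= 50L]
  if (length(common) == 0L) return(empty)
  sel_f <- fk %in% common
  sel_r <- rk %in% common
  df_f <- data.frame(km = fk[sel_f], i = which(sel_f) - 1L,
                     stringsAsFactors = FALSE)
  df_r <- data.frame(km = rk[sel_r], b = n - which(sel_r) - k + 1L,
                     stringsAsFactors = FALSE)
  pairs <- merge(df_f, df_r, by = "km")
  pairs <- pairs[pairs$b >= pairs$i, , drop = FALSE]  # arm2 right of arm1
  if (nrow(pairs) == 0L) return(empty)

  # anti-diagonal: arm1 position p pairs with arm2 position D - p
  pairs$D <- pairs$i + pairs$b + k - 1L
  cand <- lapply(split(pairs, pairs$D), function(pp) {
    c(D = pp$D[1], pmin = min(pp$i), pmax = max(pp$i) + k - 1L)
  })

  mism <- function(p, D) comp[p + 1L] != seq[D - p + 1L]

  res <- list()
  # X-drop extension scoring: a mismatch costs (1 - f) / f times a match so
  # that extension pays off only while local identity stays >= 1 - f
  mm_cost <- (1 - max_mismatch_fraction) / max(max_mismatch_fraction, 1e-6)
  xdrop <- 2 * mm_cost
  for (cc in cand) {
    D <- cc["D"]; pmin <- cc["pmin"]; pmax <- cc["pmax"]
    step_extend <- function(p0, dir) {
      # returns the argmax-score endpoint of an ungapped X-drop extension
      best <- p0; p <- p0
      score <- 0; best_score <- 0
      repeat {
        q <- p + dir
        bq <- D - q
        if (q < 0L || q > n - 1L || bq < 0L || bq > n - 1L || q >= bq) break
        score <- score + if (mism(q, D)) -mm_cost else 1
        if (score > best_score) {
          best_score <- score
          best <- q
        }
        if (best_score - score > xdrop) break
        p <- q
      }
      best
    }
    # arms may not cross the anti-diagonal midpoint
    pmax <- min(pmax, as.integer(floor((D - 1) / 2)))
    if (pmax < pmin) next
    pmax_cur <- step_extend(pmax, +1L)
    pmin_cur <- step_extend(pmin, -1L)
    pmax_cur <- min(pmax_cur, as.integer(floor((D - 1) / 2)))
    a1s <- pmin_cur; a1e <- pmax_cur + 1L
    a2s <- D - pmax_cur; a2e <- D - pmin_cur + 1L
    arm_len <- a1e - a1s
    if (arm_len < min_arm) next
    if (a2s < a1e) next
    spacer <- a2s - a1e
    if (spacer > max_spacer) next
    mmf <- sum(mism(a1s:(a1e - 1L), D))
    res[[length(res) + 1L]] <- data.frame(
      arm1_start = as.integer(a1s), arm1_end = as.integer(a1e),
      arm2_start = as.integer(a2s), arm2_end = as.integer(a2e),
      spacer_len = as.integer(spacer), arm_len = as.integer(arm_len),
      identity = unname(1 - mmf / arm_len))
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  # keep maximal non-overlapping repeats (longest arms first)
  out <- out[order(-out$arm_len), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    for (j in seq_len(i - 1L)[keep[seq_len(i - 1L)]]) {
      if (out$arm1_start[i] < out$arm2_end[j] &&
          out$arm2_end[i] > out$arm1_start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$arm1_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
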