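# small locus for fast unit tests; geometry mirrors the default layout
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, flank_len = 5000L, dup_left_len = 3000L,
               trp_len = 4000L, dup_right_len = 3000L,
               palindrome_arm_len = 2000L, palindrome_spacer_len = 600L,
               cis_morphism_offsets = c(700L, 1300L), bin_size = 100L,
               long_read_len_mean = 2000L, n_long_reads = 300L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# independent exhaustive oracle: score every state path, return the optimum
oracle_best_paths <- function(counts, states, baseline, penalty) {
  n <- length(counts)
  paths <- as.matrix(expand.grid(rep(list(seq_along(states)), n)))
  lam <- pmax(states, 0.05) / 2 * baseline
  scores <- apply(paths, 1, function(p) {
    sum(dpois(counts, lam[p], log = TRUE)) - penalty * sum(diff(p) != 0)
  })
  best <- max(scores)
  opt <- paths[abs(scores - best) <= 1e-9, , drop = FALSE]
  list(score = best,
       paths = lapply(seq_len(nrow(opt)), function(i) states[opt[i, ]]))
}

path_score <- function(cn_path, counts, states, baseline, penalty) {
  lam <- pmax(cn_path, 0.05) / 2 * baseline
  sum(dpois(counts, lam, log = TRUE)) - penalty * sum(diff(cn_path) != 0)
}

# independent brute-force walk enumeration: try every (segment, orientation)
# continuation and validate adjacencies from first principles
oracle_enumerate <- function(segments, junction_edges) {
  n <- nrow(segments)
  m <- segments$m
  edge_connects <- function(e, exit, entry) {
    any(vapply(e$variants, function(v) {
      a <- paste(v$e1, collapse = ":")
      b <- paste(v$e2, collapse = ":")
      setequal(c(a, b), c(paste(exit, collapse = ":"),
                          paste(entry, collapse = ":")))
    }, logical(1)))
  }
  results <- list()
  recurse <- function(seq_idx, seq_or, used_cnt, used_edge) {
    i <- seq_idx[length(seq_idx)]
    o <- seq_or[length(seq_or)]
    if (i == n && o == "+" && all(used_cnt == m) &&
        (length(junction_edges) == 0L || all(used_edge))) {
      results[[length(results) + 1L]] <<- list(idx = seq_idx, or = seq_or)
    }
    exit <- c(segments$id[i], if (o == "+") "tail" else "head")
    for (j in seq_len(n)) {
      if (used_cnt[j] >= m[j]) next
      for (oo in c("+", "-")) {
        entry <- c(segments$id[j], if (oo == "+") "head" else "tail")
        ref_ok <- (o == "+" && oo == "+" && j == i + 1L) ||
                  (o == "-" && oo == "-" && j == i - 1L)
        via <- if (ref_ok) 0L else {
          hits <- which(vapply(junction_edges, edge_connects, logical(1),
                               exit = exit, entry = entry))
          if (length(hits)) hits[1] else NA_integer_
        }
        if (!ref_ok && is.na(via)) next
        used_cnt[j] <- used_cnt[j] + 1L
        ue <- used_edge
        if (!ref_ok) ue[via] <- TRUE
        recurse(c(seq_idx, j), c(seq_or, oo), used_cnt, ue)
        used_cnt[j] <- used_cnt[j] - 1L
      }
    }
  }
  used_cnt <- integer(n)
  used_cnt[1] <- 1L
  recurse(1L, "+", used_cnt, logical(length(junction_edges)))
  keys <- vapply(results, function(r) {
    w <- data.frame(segment = segments$id[r$idx], or = r$or)
    canonical_walk_key(data.frame(segment = w$segment, orient = w$or))
  }, character(1))
  unique(keys)
}

# the hypothetical inverted duplication-triplication evidence fixture:
# multiplicities (1,2,3,2,1), tail-to-tail distal junction, head-to-head
# proximal junction ambiguous within the inverted-repeat pair
duptrp_evidence_fixture <- function() {
  segs <- data.frame(id = paste0("s", 1:5),
                     start = c(0, 100, 200, 350, 450) * 1000,
                     end = c(100, 200, 350, 450, 550) * 1000,
                     m = c(1L, 2L, 3L, 2L, 1L))
  prox <- list(jclass = "INV_HEAD_HEAD", breakends = c(100000, 200000),
               variants = list(list(e1 = c(seg = "s2", side = "head"),
                                    e2 = c(seg = "s3", side = "head"))))
  dist <- list(jclass = "INV_TAIL_TAIL", breakends = c(350000, 450000),
               variants = list(list(e1 = c(seg = "s3", side = "tail"),
                                    e2 = c(seg = "s4", side = "tail"))))
  segment_partition(segs, list(prox, dist))
}
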