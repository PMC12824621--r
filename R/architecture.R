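#' Build a segment partition from CN segments and junction calls
#'
#' Breakpoints are the union of copy-number step positions and junction
#' breakends, merged within `tol` bp by single-linkage clustering. Junction
#' breakends are base-precise while CN steps carry bin-level quantisation
#' plus changepoint-estimator variance, so a merged cluster is represented
#' by its median junction position when one is present. A `tol` of a few
#' bin widths absorbs the occasional multi-bin segmentation error. Each
#' resulting segment carries an allele multiplicity `m = cn - 1` under the
#' intact-homolog assumption (all pedigree evidence for these rearrangements
#' is consistent with one normal homolog). A junction breakend falling inside
#' an annotated homologous inverted-repeat pair expands into one placement
#' per repeat copy (the mapped position and its paralog).
#'
#' @param cn_segments output of [segment_cn()] (or a truth CN profile with a
#'   `cn` column).
#' @param junction_calls output of [cluster_junctions()].
#' @param repeat_annotation optional data.frame with columns `arm1_start`,
#'   `arm1_end`, `arm2_start`, `arm2_end` (e.g. from
#'   [find_inverted_repeats()]).
#' @param tol breakpoint merge tolerance in bp.
#' @return An object of class `segment_partition`: `segments` (id, start,
#'   end, m) and `junction_edges` (each with class, breakends and one or more
#'   alternative endpoint placements).
#' @export
partition_segments <- function(cn_segments, junction_calls,
                               repeat_annotation = NULL, tol = 1000L) {
  if (any(cn_segments$cn < 1L)) {
    stop("total CN < 1 (loss on both homologs) is unsupported")
  }
  lo <- min(cn_segments$start)
  hi <- max(cn_segments$end)
  cn_steps <- setdiff(unique(c(cn_segments$start, cn_segments$end)), c(lo, hi))

  be <- data.frame(pos = numeric(0), jx = integer(0), end = integer(0))
  if (nrow(junction_calls) > 0L) {
    be <- rbind(
      data.frame(pos = junction_calls$pos1, jx = seq_len(nrow(junction_calls)),
                 end = 1L),
      data.frame(pos = junction_calls$pos2, jx = seq_len(nrow(junction_calls)),
                 end = 2L))
  }

  placements <- function(pos) {
    out <- pos
    if (!is.null(repeat_annotation)) {
      for (i in seq_len(nrow(repeat_annotation))) {
        r <- repeat_annotation[i, ]
        len <- r$arm1_end - r$arm1_start
        if (pos >= r$arm1_start && pos < r$arm1_end) {
          out <- c(out, r$arm2_start + (len - (pos - r$arm1_start)))
        } else if (pos >= r$arm2_start && pos < r$arm2_end) {
          out <- c(out, r$arm1_start + (len - (pos - r$arm2_start)))
        }
      }
    }
    unique(out)
  }
  be_raw <- lapply(seq_len(nrow(be)), function(i) placements(be$pos[i]))

  # consolidate boundaries: cluster candidates within tol (single linkage);
  # junction breakends are base-precise while CN steps are bin-quantised, so
  # a cluster containing junction positions is represented by their median
  cand <- rbind(
    data.frame(pos = cn_steps,
               src = rep("cn", length(cn_steps))),
    data.frame(pos = unlist(be_raw),
               src = rep("jx", length(unlist(be_raw)))))
  bnd <- c(lo, hi)
  if (nrow(cand) > 0L) {
    cand <- cand[order(cand$pos), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(cand$pos) > tol))
    reps <- vapply(split(cand, grp), function(g) {
      if (any(g$src == "jx")) stats::median(g$pos[g$src == "jx"])
      else stats::median(g$pos)
    }, numeric(1))
    bnd <- c(lo, hi, round(reps))
  }
  bnd <- sort(unique(bnd))
  bnd <- bnd[bnd >= lo & bnd <= hi]
  # re-snap junction placements onto the consolidated boundaries
  be_place <- lapply(be_raw, function(p) {
    unique(vapply(p, function(x) bnd[which.min(abs(bnd - x))], numeric(1)))
  })

  segments <- data.frame(id = paste0("s", seq_len(length(bnd) - 1L)),
                         start = bnd[-length(bnd)], end = bnd[-1],
                         stringsAsFactors = FALSE)
  mid <- (segments$start + segments$end) / 2
  idx <- findInterval(mid, cn_segments$start)
  segments$m <- as.integer(cn_segments$cn[idx] - 1L)

  seg_at <- function(pos, side) {
    # segment whose head (start) or tail (end) lies at the boundary nearest pos
    b <- bnd[which.min(abs(bnd - pos))]
    i <- if (side == "head") match(b, segments$start)
         else match(b, segments$end)
    if (is.na(i)) NULL else segments$id[i]
  }

  edge_sides <- function(jclass) {
    switch(jclass,
           INV_TAIL_TAIL = c("tail", "tail"),
           INV_HEAD_HEAD = c("head", "head"),
           DEL_LIKE = c("tail", "head"),
           TANDEM_DUP_LIKE = c("head", "tail"),
           stop("cannot place junction class ", jclass))
  }

  junction_edges <- list()
  if (nrow(junction_calls) > 0L) {
    for (j in seq_len(nrow(junction_calls))) {
      jclass <- junction_calls$jclass[j]
      sides <- edge_sides(jclass)
      p1 <- be_place[[which(be$jx == j & be$end == 1L)]]
      p2 <- be_place[[which(be$jx == j & be$end == 2L)]]
      variants <- list()
      for (a in p1) for (b in p2) {
        s1 <- seg_at(a, sides[1]); s2 <- seg_at(b, sides[2])
        if (is.null(s1) || is.null(s2)) next
        v <- list(e1 = c(seg = s1, side = sides[1]),
                  e2 = c(seg = s2, side = sides[2]))
        variants[[length(variants) + 1L]] <- v
      }
      # dedupe variants
      sig <- vapply(variants, function(v) {
        paste(sort(c(paste(v$e1, collapse = ":"),
                     paste(v$e2, collapse = ":"))), collapse = "|")
      }, character(1))
      variants <- variants[!duplicated(sig)]
      if (length(variants) == 0L) {
        stop("junction ", j, " (", jclass, ") has no placement coinciding ",
             "with a partition boundary within tolerance")
      }
      junction_edges[[j]] <- list(id = paste0("j", j), jclass = jclass,
                                  breakends = c(junction_calls$pos1[j],
                                                junction_calls$pos2[j]),
                                  variants = variants)
    }
  }

  structure(list(segments = segments, junction_edges = junction_edges),
            class = "segment_partition")
}

#' Assemble a segment partition directly
#'
#' Low-level constructor used to state a fixture explicitly: segments with
#' multiplicities and junction edges given as segment extremities.
#'
#' @param segments data.frame with `id`, `start`, `end`, `m`.
#' @param junction_edges list of edges; each is
#'   `list(jclass =, variants = list(list(e1 = c(seg=, side=), e2 = ...)))`.
#' @return A `segment_partition`.
#' @export
segment_partition <- function(segments, junction_edges = list()) {
  stopifnot(all(c("id", "start", "end", "m") %in% names(segments)))
  for (j in seq_along(junction_edges)) {
    if (is.null(junction_edges[[j]]$id)) {
      junction_edges[[j]]$id <- paste0("j", j)
    }
  }
  structure(list(segments = segments, junction_edges = junction_edges),
            class = "segment_partition")
}

#' @export
print.segment_partition <- function(x, ...) {
  cat("segment_partition:", nrow(x$segments), "segments (m =",
      paste(x$segments$m, collapse = ","), "),",
      length(x$junction_edges), "junction edge(s)\n")
  invisible(x)
}

#' Enumerate all haplotype architectures consistent with the evidence
#'
#' Exhaustive depth-first enumeration of walks over the breakpoint graph
#' (segment extremities, reference adjacencies, junction edges). A valid walk
#' starts at the left flank in forward orientation, ends at the right flank
#' in forward orientation, traverses each segment exactly `m` times, uses at
#' least one placement of every junction edge, and flips orientation only
#' across inverted junction edges. Walks are deduplicated by canonical form
#' and returned in lexicographic order.
#'
#' @param partition a `segment_partition`.
#' @param max_walks abort with an error if more than this many walks are
#'   found (guards against combinatorial blow-up; default 64).
#' @return A list of walks; each walk is a data.frame with columns `segment`
#'   and `orient` (`"+"` forward, `"-"` inverted). Empty list (with a
#'   diagnostic attribute) when the constraints are infeasible.
#' @examples
#' segs <- data.frame(id = c("s1", "s2"), start = c(0, 100),
#'                    end = c(100, 200), m = c(1L, 1L))
#' enumerate_architectures(segment_partition(segs))
#' @export
enumerate_architectures <- function(partition, max_walks = 64L) {
  segs <- partition$segments
  n_seg <- nrow(segs)
  edges <- partition$junction_edges
  seg_idx <- stats::setNames(seq_len(n_seg), segs$id)

  # junction moves indexed by exit extremity "seg:side"
  moves <- list()
  add_move <- function(key, val) {
    moves[[key]] <<- append(moves[[key]], list(val))
  }
  for (e in seq_along(edges)) {
    for (v in edges[[e]]$variants) {
      k1 <- paste(v$e1["seg"], v$e1["side"], sep = ":")
      k2 <- paste(v$e2["seg"], v$e2["side"], sep = ":")
      add_move(k1, list(edge = e, to = v$e2))
      add_move(k2, list(edge = e, to = v$e1))
    }
  }

  walks <- list()
  m0 <- segs$m
  truncated <- FALSE

  dfs <- function(seg, orient, remaining, used, path) {
    if (truncated) return()
    # exit extremity of the current element
    exit_side <- if (orient == "+") "tail" else "head"
    at_end <- seg == n_seg && orient == "+"
    if (at_end && all(remaining == 0L) &&
        (length(edges) == 0L || all(used > 0L))) {
      if (length(walks) >= max_walks) {
        truncated <<- TRUE
        return()
      }
      walks[[length(walks) + 1L]] <<- path
      # a completed walk can in principle continue through a junction at the
      # right flank tail; keep exploring below
    }
    key <- paste(segs$id[seg], exit_side, sep = ":")
    # reference adjacency
    if (orient == "+" && seg < n_seg && remaining[seg + 1L] > 0L) {
      remaining[seg + 1L] <- remaining[seg + 1L] - 1L
      dfs(seg + 1L, "+", remaining, used,
          rbind(path, data.frame(segment = segs$id[seg + 1L], orient = "+",
                                 stringsAsFactors = FALSE)))
      remaining[seg + 1L] <- remaining[seg + 1L] + 1L
    }
    if (orient == "-" && seg > 1L && remaining[seg - 1L] > 0L) {
      remaining[seg - 1L] <- remaining[seg - 1L] - 1L
      dfs(seg - 1L, "-", remaining, used,
          rbind(path, data.frame(segment = segs$id[seg - 1L], orient = "-",
                                 stringsAsFactors = FALSE)))
      remaining[seg - 1L] <- remaining[seg - 1L] + 1L
    }
    # junction moves
    for (mv in moves[[key]]) {
      tseg <- seg_idx[[mv$to["seg"]]]
      torient <- if (mv$to["side"] == "head") "+" else "-"
      if (remaining[tseg] > 0L) {
        remaining[tseg] <- remaining[tseg] - 1L
        used[mv$edge] <- used[mv$edge] + 1L
        dfs(tseg, torient, remaining, used,
            rbind(path, data.frame(segment = segs$id[tseg], orient = torient,
                                   stringsAsFactors = FALSE)))
        used[mv$edge] <- used[mv$edge] - 1L
        remaining[tseg] <- remaining[tseg] + 1L
      }
    }
  }

  remaining <- m0
  if (remaining[1L] < 1L) {
    out <- list()
    attr(out, "diagnostic") <- "left flank has multiplicity 0"
    return(out)
  }
  remaining[1L] <- remaining[1L] - 1L
  dfs(1L, "+", remaining, integer(length(edges)),
      data.frame(segment = segs$id[1L], orient = "+",
                 stringsAsFactors = FALSE))
  if (truncated) {
    stop("more than max_walks = ", max_walks, " architectures (",
         length(walks), " found before truncation)")
  }

  # deduplicate by canonical form; deterministic lexicographic order
  keys <- vapply(walks, canonical_walk_key, character(1))
  walks <- walks[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  walks <- walks[order(keys)]
  if (length(walks) == 0L) {
    attr(walks, "diagnostic") <- "constraints infeasible: no walk satisfies multiplicities and junction usage"
  }
  walks
}

#' Canonical form of a haplotype walk
#'
#' A walk and its full reverse complement describe the same molecule; the
#' canonical key is the lexicographically smaller of the two renderings, so
#' that the pair is counted once.
#'
#' @param walk data.frame with `segment`, `orient`.
#' @return A single string key.
#' @export
canonical_walk_key <- function(walk) {
  fwd <- paste(paste0(walk$segment, walk$orient), collapse = " ")
  rc <- paste(paste0(rev(walk$segment),
                     ifelse(rev(walk$orient) == "+", "-", "+")),
              collapse = " ")
  min(fwd, rc)
}

#' Render a walk as text (inverted segments with a trailing minus)
#' @param walk data.frame with `segment`, `orient`.
#' @return A string such as `"s1 s2 s3 s4 s3- s2 s3 s4 s5"`.
#' @export
format_walk <- function(walk) {
  paste(paste0(walk$segment, ifelse(walk$orient == "-", "-", "")),
        collapse = " ")
}
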