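walk_runs <- function(walk, segments) {
  # decompose a walk into maximal reference-contiguous runs (start, end)
  idx <- match(walk$segment, segments$id)
  runs <- list()
  cur <- c(segments$start[idx[1]], segments$end[idx[1]])
  for (i in seq_along(idx)[-1]) {
    prev <- idx[i - 1L]; this <- idx[i]
    ref_adj <- (walk$orient[i - 1L] == "+" && walk$orient[i] == "+" &&
                  this == prev + 1L) ||
               (walk$orient[i - 1L] == "-" && walk$orient[i] == "-" &&
                  this == prev - 1L)
    if (ref_adj) {
      cur <- c(min(cur[1], segments$start[this]),
               max(cur[2], segments$end[this]))
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- c(segments$start[this], segments$end[this])
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs
}

#' Per-gene consequences of a haplotype architecture
#'
#' For each gene interval, reports the number of complete copies present on
#' the rearranged allele (the number of reference-contiguous runs of the walk
#' that fully contain the gene) and whether the gene is disrupted (some run
#' ends strictly inside it, i.e. a junction breakend falls within the gene).
#' A gene entirely within the triplicated segment therefore has 3 copies in
#' every architecture consistent with the evidence; a gene outside the locus
#' has 1 copy and is never disrupted.
#'
#' @param walk a walk from [enumerate_architectures()].
#' @param partition the `segment_partition` the walk was enumerated on.
#' @param genes data.frame with `name`, `start`, `end` (0-based half-open).
#' @return data.frame with `name`, `copies`, `disrupted`.
#' @export
gene_consequences <- function(walk, partition, genes) {
  segs <- partition$segments
  runs <- walk_runs(walk, segs)
  lo <- min(segs$start); hi <- max(segs$end)
  out <- lapply(seq_len(nrow(genes)), function(g) {
    gs <- genes$start[g]; ge <- genes$end[g]
    if (ge <= lo || gs >= hi) {
      return(data.frame(name = genes$name[g], copies = 1L,
                        disrupted = FALSE, stringsAsFactors = FALSE))
    }
    full <- vapply(runs, function(r) r[1] <= gs && r[2] >= ge, logical(1))
    part <- vapply(runs, function(r) {
      ov <- min(r[2], ge) - max(r[1], gs)
      ov > 0 && !(r[1] <= gs && r[2] >= ge)
    }, logical(1))
    data.frame(name = genes$name[g], copies = as.integer(sum(full)),
               disrupted = any(part), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predicted evidence of a haplotype architecture
#'
#' Scans consecutive walk elements: reference adjacencies emit nothing;
#' non-reference adjacencies emit a junction whose breakend positions and
#' strands are determined by the flanking orientations. The copy-number
#' profile is 1 (intact homolog) plus the per-segment traversal count. All
#' architectures enumerated from the same evidence predict identical output
#' -- they are evidence-equivalent by construction.
#'
#' @param walk a walk data.frame (`segment`, `orient`).
#' @param partition the `segment_partition`.
#' @return list with `junctions` (sorted data.frame as in
#'   [cluster_junctions()] minus support) and `cn_profile` (`segment`,
#'   `start`, `end`, `cn`).
#' @export
evidence_roundtrip <- function(walk, partition) {
  segs <- partition$segments
  idx <- match(walk$segment, segs$id)
  jx <- list()
  for (i in seq_along(idx)[-1]) {
    prev <- idx[i - 1L]; this <- idx[i]
    o1 <- walk$orient[i - 1L]; o2 <- walk$orient[i]
    ref_adj <- (o1 == "+" && o2 == "+" && this == prev + 1L) ||
               (o1 == "-" && o2 == "-" && this == prev - 1L)
    if (ref_adj) next
    exit_type <- if (o1 == "+") "tail" else "head"
    exit_pos <- if (o1 == "+") segs$end[prev] else segs$start[prev]
    entry_type <- if (o2 == "+") "head" else "tail"
    entry_pos <- if (o2 == "+") segs$start[this] else segs$end[this]
    jx[[length(jx) + 1L]] <- junction_from_breakends(exit_pos, exit_type,
                                                    entry_pos, entry_type)
  }
  junctions <- if (length(jx)) {
    j <- unique(do.call(rbind, jx))
    j <- j[order(j$pos1, j$pos2, j$jclass), , drop = FALSE]
    rownames(j) <- NULL
    j
  } else {
    empty_junctions()
  }
  count <- as.integer(table(factor(idx, levels = seq_len(nrow(segs)))))
  cn_profile <- data.frame(segment = segs$id, start = segs$start,
                           end = segs$end, cn = 1L + count,
                           stringsAsFactors = FALSE)
  list(junctions = junctions, cn_profile = cn_profile)
}
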