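#' Planted breakpoints for a configured rearrangement
#'
#' Returns the four breakpoint positions (0-based) used by the simulator:
#' proximal pair `pb1 < pb2` and distal pair `db1 < db2`. With
#' `proximal_in_palindrome = FALSE`, `pb1`/`pb2` are the `dup_left` and `trp`
#' segment starts; with `TRUE` they are paralogous positions inside arm 1 and
#' arm 2, midway between the cis-morphism sites.
#'
#' @param ref a [build_reference()] object.
#' @return Named integer vector `c(pb1, pb2, db1, db2)`.
#' @export
planted_breakpoints <- function(ref) {
  layout <- ref$layout
  cfg <- ref$config
  db1 <- layout$start[layout$id == "dup_right"]
  db2 <- layout$end[layout$id == "dup_right"]
  if (cfg$proximal_in_palindrome) {
    if (is.null(ref$sites)) {
      stop("proximal_in_palindrome requires cis-morphism sites")
    }
    A <- cfg$palindrome_arm_len
    u <- as.integer(round(mean(cfg$cis_morphism_offsets)))
    pb1 <- layout$start[layout$id == "palindrome_arm_1"] + u
    pb2 <- layout$start[layout$id == "palindrome_arm_2"] + (A - u)
  } else {
    pb1 <- layout$start[layout$id == "dup_left"]
    pb2 <- layout$start[layout$id == "trp"]
  }
  c(pb1 = as.integer(pb1), pb2 = as.integer(pb2),
    db1 = as.integer(db1), db2 = as.integer(db2))
}

arch_runs <- function(arch_id, bp, L) {
  p <- unname(bp)
  pb1 <- p[1]; pb2 <- p[2]; db1 <- p[3]; db2 <- p[4]
  run <- function(s, e, o) list(start = s, end = e, orient = o)
  switch(arch_id,
    REF = list(run(0L, L, "+")),
    TANDEM_DUP = list(run(0L, db2, "+"), run(pb1, L, "+")),
    # the four evidence-equivalent inverted duplication-triplications:
    # [0,d1] + revcomp([p2,d2]) + [p1,L]; the central inverted copy [p2,d2]
    # grows from DUPTRP_1 (trp only) to DUPTRP_4 (whole dup-trp-dup span)
    DUPTRP_1 = list(run(0L, db2, "+"), run(pb2, db1, "-"), run(pb1, L, "+")),
    DUPTRP_2 = list(run(0L, db2, "+"), run(pb1, db1, "-"), run(pb2, L, "+")),
    DUPTRP_3 = list(run(0L, db1, "+"), run(pb2, db2, "-"), run(pb1, L, "+")),
    DUPTRP_4 = list(run(0L, db1, "+"), run(pb1, db2, "-"), run(pb2, L, "+")),
    DEL_INV = list(run(0L, pb1, "+"), run(pb2, db1, "-"), run(db2, L, "+")),
    stop("unknown architecture_id: ", arch_id))
}

# junctions implied by consecutive runs; breakends ordered a <= b
runs_to_junctions <- function(runs, chrom = "chrSim") {
  if (length(runs) < 2L) {
    return(empty_junctions(chrom))
  }
  out <- list()
  for (i in seq_len(length(runs) - 1L)) {
    u <- runs[[i]]; v <- runs[[i + 1L]]
    exit_type <- if (u$orient == "+") "tail" else "head"
    exit_pos <- if (u$orient == "+") u$end else u$start
    entry_type <- if (v$orient == "+") "head" else "tail"
    entry_pos <- if (v$orient == "+") v$start else v$end
    out[[i]] <- junction_from_breakends(exit_pos, exit_type,
                                        entry_pos, entry_type, chrom)
  }
  do.call(rbind, out)
}

empty_junctions <- function(chrom = "chrSim") {
  data.frame(chrom1 = character(0), pos1 = integer(0), strand1 = character(0),
             chrom2 = character(0), pos2 = integer(0), strand2 = character(0),
             jclass = character(0), stringsAsFactors = FALSE)
}

junction_from_breakends <- function(x, xtype, y, ytype, chrom = "chrSim") {
  # order breakends by position; strands follow the read-pair convention:
  # head-head (+,+), tail-tail (-,-), del-like (+,-), tandem-dup-like (-,+)
  be <- data.frame(pos = c(x, y), type = c(xtype, ytype),
                   stringsAsFactors = FALSE)
  be <- be[order(be$pos, be$type), ]
  a <- be[1, ]; b <- be[2, ]
  if (a$type == "tail" && b$type == "tail") {
    jclass <- "INV_TAIL_TAIL"; s <- c("-", "-")
  } else if (a$type == "head" && b$type == "head") {
    jclass <- "INV_HEAD_HEAD"; s <- c("+", "+")
  } else if (a$type == "tail" && b$type == "head") {
    jclass <- "DEL_LIKE"; s <- c("+", "-")
  } else {
    jclass <- "TANDEM_DUP_LIKE"; s <- c("-", "+")
  }
  data.frame(chrom1 = chrom, pos1 = as.integer(a$pos), strand1 = s[1],
             chrom2 = chrom, pos2 = as.integer(b$pos), strand2 = s[2],
             jclass = jclass, stringsAsFactors = FALSE)
}

runs_to_cn_profile <- function(runs, L, chrom = "chrSim") {
  bnd <- sort(unique(c(0L, L,
                       unlist(lapply(runs, function(r) c(r$start, r$end))))))
  starts <- bnd[-length(bnd)]
  ends <- bnd[-1]
  cn <- vapply(seq_along(starts), function(i) {
    mid <- (starts[i] + ends[i]) / 2
    1L + sum(vapply(runs, function(r) r$start <= mid && mid < r$end,
                    logical(1)))
  }, integer(1))
  # merge equal-CN neighbours
  keep <- c(TRUE, diff(cn) != 0)
  grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
  data.frame(chrom = chrom,
             start = as.integer(vapply(split(starts, grp), min, numeric(1))),
             end = as.integer(vapply(split(ends, grp), max, numeric(1))),
             cn = as.integer(vapply(split(cn, grp), function(z) z[1], integer(1))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply a rearrangement architecture to the simulated reference
#'
#' Constructs the rearranged haplotype for `architecture_id` (taken from the
#' configuration unless overridden) together with its ground truth: the
#' haplotype walk, the implied breakpoint junctions, and the constitutional
#' total copy-number profile (one rearranged plus one intact homolog).
#'
#' For every `DUPTRP_k` the rearranged allele is
#' `[0, d1] + revcomp([p2, d2]) + [p1, L]` with `{p1, p2}` the proximal and
#' `{d1, d2}` the distal breakpoint pair; the four values of `k` are the four
#' assignments that explain identical junction and depth evidence. Each yields
#' total CN (3, 4, 3) over the duplicated/triplicated/duplicated spans, exactly
#' two distinct junctions, and a tail-to-tail (-/-) distal junction.
#'
#' @param ref a [build_reference()] object.
#' @param architecture_id optional override of `ref$config$architecture_id`.
#' @return A list of class `duptrp_truth` with elements `haplotype` (character
#'   vector of bases), `runs` (reference intervals + orientation composing the
#'   allele), `walk` (data.frame: segment id, orientation, over the breakpoint
#'   partition), `segments` (the partition), `truth_junctions`,
#'   `truth_cn_profile`, `breakpoints`, and `config`.
#' @examples
#' ref <- build_reference(sim_config(seed = 1, flank_len = 2000,
#'   dup_left_len = 800, trp_len = 1200, dup_right_len = 800,
#'   palindrome_arm_len = 600, palindrome_spacer_len = 200,
#'   cis_morphism_offsets = c(150, 450)))
#' tr <- apply_architecture(ref, "DUPTRP_1")
#' tr$truth_cn_profile
#' @export
apply_architecture <- function(ref, architecture_id = NULL) {
  stopifnot(inherits(ref, "duptrp_reference"))
  arch <- architecture_id %||% ref$config$architecture_id
  if (!arch %in% duptrp_architectures()) {
    stop("unknown architecture_id: ", arch)
  }
  L <- length(ref$seq)
  bp <- planted_breakpoints(ref)
  runs <- arch_runs(arch, bp, L)
  hap <- unlist(lapply(runs, function(r) {
    v <- ref$seq[(r$start + 1L):r$end]
    if (r$orient == "-") revcomp_chars(v) else v
  }), use.names = FALSE)

  jx <- runs_to_junctions(runs)
  cnp <- runs_to_cn_profile(runs, L)

  # segment partition at the planted breakpoints, plus the walk over it
  bnd <- sort(unique(c(0L, unname(bp), L)))
  segs <- data.frame(id = paste0("s", seq_len(length(bnd) - 1L)),
                     start = bnd[-length(bnd)], end = bnd[-1],
                     stringsAsFactors = FALSE)
  walk <- do.call(rbind, lapply(runs, function(r) {
    inside <- segs$start >= r$start & segs$end <= r$end
    ids <- segs$id[inside]
    if (r$orient == "-") ids <- rev(ids)
    data.frame(segment = ids, orient = r$orient, stringsAsFactors = FALSE)
  }))

  structure(list(haplotype = hap, runs = runs, walk = walk, segments = segs,
                 truth_junctions = jx, truth_cn_profile = cnp,
                 breakpoints = bp, architecture_id = arch,
                 config = ref$config),
            class = "duptrp_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.duptrp_truth <- function(x, ...) {
  cat("duptrp_truth:", x$architecture_id, "-", length(x$haplotype),
      "bp allele,", nrow(x$truth_junctions), "junction(s)\n")
  invisible(x)
}
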