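test_that("flat diploid evidence partitions into one segment with m = 1", {
  cn <- data.frame(chrom = "chrSim", start = 0L, end = 10000L, cn = 2L)
  part <- partition_segments(cn, cluster_junctions(
    data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
               chrom2 = character(0), start2 = integer(0), end2 = integer(0),
               name = character(0), score = integer(0),
               strand1 = character(0), strand2 = character(0))))
  expect_identical(nrow(part$segments), 1L)
  expect_identical(part$segments$m, 1L)
  walks <- enumerate_architectures(part)
  expect_length(walks, 1L)
  expect_identical(format_walk(walks[[1]]), "s1")
})

test_that("the stepped 2-3-4-3-2 profile gives multiplicities (1,2,3,2,1)", {
  cn <- data.frame(chrom = "chrSim",
                   start = c(0, 100, 200, 350, 450) * 1000,
                   end = c(100, 200, 350, 450, 550) * 1000,
                   cn = c(2L, 3L, 4L, 3L, 2L))
  jx <- data.frame(chrom1 = "chrSim", pos1 = c(100000L, 350000L),
                   strand1 = c("+", "-"), chrom2 = "chrSim",
                   pos2 = c(200000L, 450000L), strand2 = c("+", "-"),
                   support = 10L,
                   jclass = c("INV_HEAD_HEAD", "INV_TAIL_TAIL"))
  part <- partition_segments(cn, jx)
  expect_identical(part$segments$m, c(1L, 2L, 3L, 2L, 1L))
  expect_length(part$junction_edges, 2L)
})

test_that("copy-number loss on both homologs is rejected", {
  cn <- data.frame(chrom = "chrSim", start = 0L, end = 1000L, cn = 0L)
  expect_error(partition_segments(cn, empty_junctions()), "unsupported")
})

test_that("a breakend inside the annotated repeat expands into paralogous placements", {
  # proximal breakends at paralogous positions inside arm1/arm2
  cfg <- small_config(proximal_in_palindrome = TRUE)
  ref <- build_reference(cfg)
  tr <- apply_architecture(ref, "DUPTRP_1")
  bp <- tr$breakpoints
  cn <- tr$truth_cn_profile
  jx <- data.frame(chrom1 = "chrSim", pos1 = c(bp["pb1"], bp["db1"]),
                   strand1 = c("+", "-"), chrom2 = "chrSim",
                   pos2 = c(bp["pb2"], bp["db2"]), strand2 = c("+", "-"),
                   support = 10L,
                   jclass = c("INV_HEAD_HEAD", "INV_TAIL_TAIL"))
  arms <- data.frame(
    arm1_start = layout_bounds(ref$layout, "palindrome_arm_1")[1],
    arm1_end = layout_bounds(ref$layout, "palindrome_arm_1")[2],
    arm2_start = layout_bounds(ref$layout, "palindrome_arm_2")[1],
    arm2_end = layout_bounds(ref$layout, "palindrome_arm_2")[2])
  part <- partition_segments(cn, jx, repeat_annotation = arms, tol = 100L)
  prox <- part$junction_edges[[1]]
  expect_gte(length(prox$variants), 2L)
  # enumeration still yields the four evidence-equivalent structures
  expect_length(enumerate_architectures(part), 4L)
})

test_that("enumeration on the four-structure fixture matches the brute-force oracle", {
  part <- duptrp_evidence_fixture()
  walks <- enumerate_architectures(part)
  expect_length(walks, 4L)
  keys <- vapply(walks, canonical_walk_key, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  oracle <- oracle_enumerate(part$segments, part$junction_edges)
  expect_setequal(keys, oracle)
  # the four structures differ exactly in the span of the inverted centre
  expect_setequal(vapply(walks, format_walk, character(1)),
                  c("s1 s2 s3 s4 s3- s2 s3 s4 s5",
                    "s1 s2 s3 s4 s3- s2- s3 s4 s5",
                    "s1 s2 s3 s4- s3- s2 s3 s4 s5",
                    "s1 s2 s3 s4- s3- s2- s3 s4 s5"))
})

test_that("enumeration equals the oracle on random small instances", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(3:5, 1)
    m <- c(1L, sample(1:3, n - 2, replace = TRUE), 1L)
    segs <- data.frame(id = paste0("s", 1:n), start = (0:(n - 1)) * 1000,
                       end = (1:n) * 1000, m = m)
    edges <- list()
    for (e in seq_len(sample(0:2, 1))) {
      cls <- sample(c("INV_HEAD_HEAD", "INV_TAIL_TAIL",
                      "TANDEM_DUP_LIKE", "DEL_LIKE"), 1)
      sides <- switch(cls, INV_HEAD_HEAD = c("head", "head"),
                      INV_TAIL_TAIL = c("tail", "tail"),
                      TANDEM_DUP_LIKE = c("head", "tail"),
                      DEL_LIKE = c("tail", "head"))
      picks <- sample(segs$id, 2)
      edges[[length(edges) + 1L]] <- list(
        jclass = cls,
        variants = list(list(e1 = c(seg = picks[1], side = sides[1]),
                             e2 = c(seg = picks[2], side = sides[2]))))
    }
    part <- segment_partition(segs, edges)
    walks <- tryCatch(enumerate_architectures(part, max_walks = 500L),
                      error = function(e) NULL)
    if (is.null(walks)) next  # blow-up guard triggered; not comparable
    keys <- vapply(walks, canonical_walk_key, character(1))
    oracle <- oracle_enumerate(part$segments, part$junction_edges)
    expect_setequal(keys, oracle)
  }
})

test_that("a single tandem-duplication junction yields exactly one walk", {
  segs <- data.frame(id = paste0("s", 1:3), start = c(0, 1000, 2000),
                     end = c(1000, 2000, 3000), m = c(1L, 2L, 1L))
  edge <- list(jclass = "TANDEM_DUP_LIKE",
               variants = list(list(e1 = c(seg = "s2", side = "head"),
                                    e2 = c(seg = "s2", side = "tail"))))
  part <- segment_partition(segs, list(edge))
  walks <- enumerate_architectures(part)
  expect_length(walks, 1L)
  expect_identical(format_walk(walks[[1]]), "s1 s2 s2 s3")
  rt <- evidence_roundtrip(walks[[1]], part)
  expect_identical(rt$junctions$jclass, "TANDEM_DUP_LIKE")
  expect_identical(rt$cn_profile$cn, c(2L, 3L, 2L))
})

test_that("infeasible constraints return an empty set with a diagnostic", {
  segs <- data.frame(id = paste0("s", 1:3), start = c(0, 1000, 2000),
                     end = c(1000, 2000, 3000), m = c(1L, 3L, 1L))
  edge <- list(jclass = "INV_TAIL_TAIL",
               variants = list(list(e1 = c(seg = "s2", side = "tail"),
                                    e2 = c(seg = "s2", side = "tail"))))
  part <- segment_partition(segs, list(edge))
  walks <- enumerate_architectures(part)
  expect_length(walks, 0L)
  expect_match(attr(walks, "diagnostic"), "infeasible")
})

test_that("exceeding max_walks raises a truncation error", {
  part <- duptrp_evidence_fixture()
  expect_error(enumerate_architectures(part, max_walks = 2L), "max_walks")
})

test_that("walks conserve length and are evidence-equivalent", {
  part <- duptrp_evidence_fixture()
  walks <- enumerate_architectures(part)
  seg_len <- part$segments$end - part$segments$start
  lens <- vapply(walks, function(w) {
    sum(seg_len[match(w$segment, part$segments$id)])
  }, numeric(1))
  expect_identical(length(unique(lens)), 1L)
  expect_identical(lens[1], sum(seg_len * part$segments$m))
  rts <- lapply(walks, evidence_roundtrip, partition = part)
  for (i in 2:4) expect_identical(rts[[i]], rts[[1]])
  expect_identical(rts[[1]]$cn_profile$cn, c(2L, 3L, 4L, 3L, 2L))
  expect_identical(sort(rts[[1]]$junctions$jclass),
                   c("INV_HEAD_HEAD", "INV_TAIL_TAIL"))
})

test_that("gene dosage and disruption follow the walk geometry", {
  part <- duptrp_evidence_fixture()
  walks <- enumerate_architectures(part)
  genes <- data.frame(
    name = c("geneA_trp", "flank_gene", "outside", "straddles_distal"),
    start = c(250000, 10000, 900000, 340000),
    end = c(300000, 20000, 910000, 360000))
  for (w in walks) {
    gc <- gene_consequences(w, part, genes)
    expect_identical(gc$copies[gc$name == "geneA_trp"], 3L)
    expect_false(gc$disrupted[gc$name == "geneA_trp"])
    expect_identical(gc$copies[gc$name == "flank_gene"], 1L)
    expect_false(gc$disrupted[gc$name == "flank_gene"])
    expect_identical(gc$copies[gc$name == "outside"], 1L)
    expect_false(gc$disrupted[gc$name == "outside"])
    # a gene straddling a used junction breakend has a severed copy in every
    # evidence-equivalent walk (junction usage counts are shared); its intact
    # copies number m - 1
    expect_identical(gc$copies[gc$name == "straddles_distal"], 2L)
    expect_true(gc$disrupted[gc$name == "straddles_distal"])
  }
})
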