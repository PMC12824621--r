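test_that("configuration invariants are enforced", {
  expect_error(sim_config(flank_len = 0), "lengths")
  expect_error(sim_config(mosaic_fraction = 1.2), "mosaic_fraction")
  expect_error(sim_config(arm_identity = 0), "arm_identity")
  expect_error(sim_config(cis_morphism_offsets = c(0, 500)),
               "strictly inside")
  expect_no_error(sim_config(arm_identity = 0.1, palindrome_arm_len = 100,
                             cis_morphism_offsets = NULL))
  expect_error(sim_config(arm_identity = 0.001, palindrome_arm_len = 10,
                          cis_morphism_offsets = c(2, 5)),
               "incompatible")
  expect_error(sim_config(architecture_id = "NOPE"), "unknown architecture")
})

test_that("arm 2 is the reverse complement of arm 1 up to planted divergence", {
  # identity 1, no cis-morphisms: exact reverse complement
  cfg <- small_config(arm_identity = 1, cis_morphism_offsets = NULL)
  ref <- build_reference(cfg)
  a1 <- layout_bounds(ref$layout, "palindrome_arm_1")
  a2 <- layout_bounds(ref$layout, "palindrome_arm_2")
  arm1 <- ref$seq[(a1[1] + 1):a1[2]]
  arm2 <- ref$seq[(a2[1] + 1):a2[2]]
  expect_identical(arm2, revcomp_chars(arm1))

  # identity 0.998 on a 10 kb arm: exactly 20 mismatching positions,
  # counted by brute-force comparison of arm1 vs revcomp(arm2)
  cfg <- sim_config(seed = 7, flank_len = 2000, dup_left_len = 1000,
                    trp_len = 1000, dup_right_len = 1000,
                    palindrome_arm_len = 10000, palindrome_spacer_len = 500,
                    arm_identity = 0.998, cis_morphism_offsets = NULL)
  ref <- build_reference(cfg)
  a1 <- layout_bounds(ref$layout, "palindrome_arm_1")
  a2 <- layout_bounds(ref$layout, "palindrome_arm_2")
  arm1 <- ref$seq[(a1[1] + 1):a1[2]]
  arm2 <- ref$seq[(a2[1] + 1):a2[2]]
  expect_identical(sum(arm1 != revcomp_chars(arm2)), 20L)
})

test_that("cis-morphism sites are paralogous, distinct, and 4.2 kb apart at defaults", {
  ref <- build_reference(sim_config(seed = 1))
  expect_identical(nrow(ref$sites), 2L)
  expect_true(all(ref$sites$arm1_allele != ref$sites$arm2_allele))
  expect_identical(diff(ref$sites$arm1_pos), 4200L)
  expect_identical(diff(ref$sites$arm2_pos), -4200L)  # mirrored in arm 2
  # the arm-1-frame reading of arm 2 at the paralogous position is arm2_allele
  expect_identical(comp_base(ref$seq[ref$sites$arm2_pos + 1L]),
                   ref$sites$arm2_allele)
})

test_that("reference layout tiles the locus without gaps", {
  ref <- build_reference(small_config())
  expect_identical(ref$layout$start[-1], ref$layout$end[-nrow(ref$layout)])
  expect_identical(ref$layout$start[1], 0L)
  expect_identical(ref$layout$end[nrow(ref$layout)], length(ref$seq))
})

test_that("REF architecture reproduces the reference with flat CN 2", {
  ref <- build_reference(small_config())
  tr <- apply_architecture(ref, "REF")
  expect_identical(tr$haplotype, ref$seq)
  expect_identical(nrow(tr$truth_junctions), 0L)
  expect_identical(tr$truth_cn_profile$cn, 2L)
})

test_that("every DUPTRP architecture gives CN (3,4,3), two junctions, -/- distal", {
  ref <- build_reference(small_config())
  for (arch in paste0("DUPTRP_", 1:4)) {
    tr <- apply_architecture(ref, arch)
    cnp <- tr$truth_cn_profile
    cn_at <- function(id) {
      b <- layout_bounds(ref$layout, id)
      mid <- mean(b)
      cnp$cn[which(cnp$start <= mid & cnp$end > mid)]
    }
    expect_identical(c(cn_at("dup_left"), cn_at("trp"), cn_at("dup_right")),
                     c(3L, 4L, 3L), info = arch)
    expect_identical(nrow(tr$truth_junctions), 2L, info = arch)
    distal <- tr$truth_junctions[which.max(tr$truth_junctions$pos2), ]
    expect_identical(distal$jclass, "INV_TAIL_TAIL", info = arch)
    expect_identical(c(distal$strand1, distal$strand2), c("-", "-"))
    # junction positions coincide with CN step positions
    steps <- setdiff(unique(c(cnp$start, cnp$end)), c(0L, length(ref$seq)))
    expect_true(all(c(tr$truth_junctions$pos1, tr$truth_junctions$pos2)
                    %in% steps), info = arch)
    # conservation: walk length equals allele length
    segs <- tr$segments
    seg_len <- segs$end - segs$start
    expect_identical(sum(seg_len[match(tr$walk$segment, segs$id)]),
                     length(tr$haplotype))
  }
})

test_that("a gene fully inside the triplicated segment has 3 copies on the allele", {
  ref <- build_reference(small_config())
  trp <- layout_bounds(ref$layout, "trp")
  gene <- data.frame(name = "geneA", start = trp[1] + 500,
                     end = trp[2] - 500)
  for (arch in paste0("DUPTRP_", 1:4)) {
    tr <- apply_architecture(ref, arch)
    part <- segment_partition(cbind(tr$segments, m = NA))
    gc <- gene_consequences(tr$walk, part, gene)
    expect_identical(gc$copies, 3L, info = arch)
    expect_false(gc$disrupted)
  }
})

test_that("depth means follow the mosaic dosage model", {
  ref <- build_reference(small_config())
  tr <- apply_architecture(ref, "DUPTRP_1")
  cfg <- ref$config
  # f = 1 constitutional: flank ratio ~ 1, trp ratio ~ 2
  bins <- simulate_depth(tr, f = 1)
  trp <- layout_bounds(ref$layout, "trp")
  flank_mean <- mean(bins$count[bins$end <= 5000])
  trp_mean <- mean(bins$count[bins$start >= trp[1] & bins$end <= trp[2]])
  expect_equal(flank_mean / (2 * cfg$haploid_depth), 1, tolerance = 0.1)
  expect_equal(trp_mean / flank_mean, 2, tolerance = 0.15)

  # f = 0.35 dup-only segment: mean ratio (2 + 0.35)/2 = 1.175,
  # Monte-Carlo over >= 1e5 bins at the dup mean
  mu <- cfg$haploid_depth * (2 + 0.35 * (3 - 2))
  set.seed(42)
  counts <- rpois(1e5, mu)
  expect_equal(mean(counts) / (2 * cfg$haploid_depth), 1.175,
               tolerance = 0.005)
  # and the simulator draws from that mean
  bins35 <- simulate_depth(tr, f = 0.35, seed = 11)
  dup <- layout_bounds(ref$layout, "dup_left")
  dup_mean <- mean(bins35$count[bins35$start >= dup[1] &
                                  bins35$end <= dup[2]])
  expect_equal(dup_mean / (2 * cfg$haploid_depth), 1.175, tolerance = 0.06)
})

test_that("junction evidence carries truth strands and exact positions at jitter 0", {
  ref <- build_reference(small_config())
  tr <- apply_architecture(ref, "DUPTRP_3")
  ev <- simulate_junction_evidence(tr, n_pairs = 8, jitter = 0)
  expect_identical(nrow(ev), 16L)
  for (i in seq_len(nrow(tr$truth_junctions))) {
    sub <- ev[ev$strand1 == tr$truth_junctions$strand1[i] &
                ev$start1 == tr$truth_junctions$pos1[i], ]
    expect_identical(nrow(sub), 8L)
    expect_true(all(sub$start2 == tr$truth_junctions$pos2[i]))
    expect_true(all(sub$strand2 == tr$truth_junctions$strand2[i]))
  }
  # tail-to-tail rows are (-,-); head-to-head rows are (+,+)
  tt <- ev[ev$start2 == max(ev$start2), ]
  expect_true(all(tt$strand1 == "-" & tt$strand2 == "-"))
  hh <- ev[ev$start1 == min(ev$start1), ]
  expect_true(all(hh$strand1 == "+" & hh$strand2 == "+"))
  # REF: empty evidence
  expect_identical(nrow(simulate_junction_evidence(
    apply_architecture(ref, "REF"))), 0L)
})

test_that("long reads from the intact haplotype are never chimeric", {
  cfg <- small_config(seed = 3)
  ref <- build_reference(cfg)
  tr <- apply_architecture(ref, "REF")
  lr <- simulate_long_reads(ref, tr, n = 200, error_rate = 0)
  obs <- lr$observations
  wide <- split(obs, obs$read_id)
  for (o in wide) {
    if (length(unique(o$site_id)) == 2L) {
      arm <- ifelse(o$allele == ref$sites$arm1_allele[
        match(o$site_id, ref$sites$site_id)], "arm1", "arm2")
      expect_identical(length(unique(arm)), 1L)
    }
  }
  # n = 0: empty table
  lr0 <- simulate_long_reads(ref, tr, n = 0)
  expect_identical(nrow(lr0$observations), 0L)
})

test_that("reads across a palindrome-internal breakpoint show chimeric alleles", {
  cfg <- small_config(seed = 4, proximal_in_palindrome = TRUE)
  ref <- build_reference(cfg)
  tr <- apply_architecture(ref, "DUPTRP_2")
  lr <- simulate_long_reads(ref, tr, n = 400, error_rate = 0)
  obs <- lr$observations
  s <- ref$sites[order(ref$sites$arm1_pos), ]
  per_read <- split(obs, obs$read_id)
  chim <- vapply(per_read, function(o) {
    o <- o[!duplicated(o$site_id), ]
    if (length(unique(o$site_id)) < 2L) return(FALSE)
    a <- o$allele[match(s$site_id, o$site_id)]
    a[1] == s$arm2_allele[1] && a[2] == s$arm1_allele[2]
  }, logical(1))
  expect_gt(sum(chim), 0)
  # chimeric reads come from the rearranged molecule and span the junction
  jmol <- sum(vapply(tr$runs[1:2], function(r) r$end - r$start, numeric(1)))
  rd <- lr$reads[lr$reads$read_id %in% names(per_read)[chim], ]
  expect_true(all(rd$molecule == "rearranged"))
  expect_true(all(rd$start < jmol & rd$start + rd$length > jmol))
})

test_that("short length model warns that phasing is impossible", {
  cfg <- small_config()
  ref <- build_reference(cfg)
  tr <- apply_architecture(ref, "REF")
  expect_warning(simulate_long_reads(ref, tr, n = 1, len_mean = 500),
                 "phasing will be impossible")
})

test_that("expression simulator plants the dosage effect where asked", {
  # dosage_fc = 1: index indistinguishable in expectation (mean over seeds)
  fc1 <- vapply(1:10, function(s) {
    sim <- simulate_expression(50, 1, 0.1, s)
    fold_above_mean(housekeeping_normalize(sim$tpm, "GAPDH"),
                    "INDEX", "ATP6V0C")
  }, numeric(1))
  expect_equal(mean(fc1), 1, tolerance = 0.1)
  # constitutional CN 4 under the naive dosage model plants fc 2
  expect_identical(expected_dosage_fc(4), 2)
  sim <- simulate_expression(50, expected_dosage_fc(4), 0.1, 1)
  expect_identical(sim$target_gene, "ATP6V0C")
  # housekeeping genes unscaled: their cohort stats include the index
  norm <- housekeeping_normalize(sim$tpm, "GAPDH")
  expect_true(abs(expression_zscore(norm, "INDEX", "ACTB")) < 4)
})

test_that("population CNV planting is truth-driven", {
  target <- c(2503226, 2529370)
  # no duplications planted: nothing overlaps the target
  cnv0 <- simulate_population_cnv(500000, n_dup = 0, target, seed = 1)
  scr0 <- screen_population(cnv0, target)
  expect_identical(sum(scr0$class_counts), 0L)
  # 19 planted duplications recovered exactly
  cnv <- simulate_population_cnv(500000, n_dup = 19, target, seed = 1)
  scr <- screen_population(cnv, target)
  expect_identical(unname(scr$class_counts["DUP"]), 19L)
  expect_identical(unname(scr$class_counts["TRIP"]), 0L)
  # sizes bounded below 10 kb are screened out entirely
  cnv_small <- simulate_population_cnv(500000, n_dup = 19, target,
                                       size_range = c(3000, 9000), seed = 1)
  expect_identical(sum(screen_population(cnv_small, target)$class_counts), 0L)
})

test_that("emitted files re-parse to the in-memory objects", {
  ref <- build_reference(small_config())
  tr <- apply_architecture(ref, "DUPTRP_1")
  d <- withr::local_tempdir()

  bins <- simulate_depth(tr)
  f <- file.path(d, "bins.tsv")
  write_depth_tsv(bins, f)
  expect_identical(read_depth_tsv(f), bins)

  ev <- simulate_junction_evidence(tr)
  f <- file.path(d, "ev.bedpe")
  write_bedpe(ev, f)
  expect_identical(read_bedpe(f), ev)

  f <- file.path(d, "layout.bed")
  write_bed(ref$layout, f)
  bed <- read_bed(f)
  expect_identical(bed$start, ref$layout$start)
  expect_identical(bed$name, ref$layout$id)

  f <- file.path(d, "sites.tsv")
  write_tsv(ref$sites, f)
  expect_identical(read_tsv(f), ref$sites)

  f <- file.path(d, "ref.fa")
  write_fasta(ref$seq, f)
  back <- read_fasta(f)
  expect_identical(unname(back), paste(ref$seq, collapse = ""))
})

test_that("malformed BEDPE rows are reported with line numbers", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.bedpe")
  writeLines(c("c\t1\t2\tc\t5\t6\tn\t60\t+\t-",
               "c\t1\t2\tc\t5\t6\tn\t60",
               "c\tx\t2\tc\t5\t6\tn\t60\t+\t-"), f)
  expect_error(read_bedpe(f, strict = TRUE), "line\\(s\\): 2, 3")
  expect_warning(ok <- read_bedpe(f, strict = FALSE), "skipped")
  expect_identical(nrow(ok), 1L)
})
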