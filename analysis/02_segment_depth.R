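#!/usr/bin/env Rscript
# Segment the binned depth into integer copy numbers (the stepped 2-3-4-3-2
# profile) and estimate the mosaic fraction a carrier parent would show.

suppressPackageStartupMessages(library(duptrp))

bins <- read_depth_tsv("results/depth_bins.tsv")
segs <- segment_cn(bins, baseline_strategy = "flank_median")
write_tsv(segs, "results/cn_segments.tsv")
message("copy-number segments:")
print(segs)

truth <- read_tsv("results/truth_cn_profile.tsv")
message("truth step positions: ",
        paste(setdiff(unique(c(truth$start, truth$end)),
                      range(c(truth$start, truth$end))), collapse = ", "))

# mosaic interpretation of the triplicated segment ratio, and the
# constitutional check: a dup-only segment at r = 1.5 implies f = 1
trp_seg <- segs[segs$cn == 4L, ][1, ]
baseline <- attr(normalize_depth(bins, "flank_median"), "diploid_baseline")
est <- estimate_mosaic_fraction(trp_seg$mean_ratio, k = 2,
                                n_bins = trp_seg$n_bins,
                                bin_mean = baseline)
message(sprintf(
  "triplicated segment r = %.3f -> fraction of cells carrying the allele: %.2f (95%% CI %.2f-%.2f)",
  trp_seg$mean_ratio, est$f, est$ci_low, est$ci_high))
write_tsv(data.frame(segment = "trp", r = trp_seg$mean_ratio, f = est$f,
                     ci_low = est$ci_low, ci_high = est$ci_high),
          "results/mosaic_estimate.tsv")
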