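#!/usr/bin/env Rscript
# Cohort interval analytics on the published per-individual SV sizes and
# breakpoints, and a population screen of the simulated CNV call table.

suppressPackageStartupMessages(library(duptrp))

# per-individual duplication/triplication sizes (kb)
dup_kb <- c(448, 704, 640, 918, 230, 157, 187, 378, 514, 514, 514)
trp_kb <- c(30, 179, 317, 811, 64, 85, 105, 296, 250, 250, 250)
s_dup <- size_summary(dup_kb)
s_trp <- size_summary(trp_kb)
message(sprintf("duplication sizes: %g-%g kb (median %g)",
                s_dup["min"], s_dup["max"], s_dup["median"]))
message(sprintf("triplication sizes: %g-%g kb (median %g)",
                s_trp["min"], s_trp["max"], s_trp["median"]))

# minimal region of triplication overlap, bounded by the most distal
# proximal breakpoint and the most proximal distal breakpoint
cohort <- data.frame(
  individual = paste0("ind", 1:5),
  start = c(2503226, 2495000, 2480000, 2470000, 2460000),
  end = c(2540000, 2529370, 2600000, 2700000, 2650000))
mro <- minimal_region_of_overlap(cohort)
message(sprintf("minimal region of overlap: g.%d-%d (%.1f kb)",
                mro["start"], mro["end"],
                interval_length_kb(mro["start"], mro["end"], 1)))
write_tsv(data.frame(start = mro["start"], end = mro["end"],
                     kb = interval_length_kb(mro["start"], mro["end"], 1)),
          "results/mro.tsv")

# population screen at a 10 kb size threshold
cnv <- read_tsv("results/population_cnv.tsv")
scr <- screen_population(cnv, c(2503226, 2529370), min_size = 10000)
write_tsv(scr$hits, "results/screen_hits.tsv")
message("population screen hits by class: ",
        paste(names(scr$class_counts), scr$class_counts, sep = "=",
              collapse = ", "))
message(sprintf("observed duplication copy-ratio range: %.2f-%.2f",
                min(scr$hits$copy_ratio), max(scr$hits$copy_ratio)))
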