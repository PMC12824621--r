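#!/usr/bin/env Rscript
# Detect the inverted-repeat pair from sequence alone, then localize the
# proximal breakpoint between the two cis-morphism sites using the
# long-read allele observations.

suppressPackageStartupMessages(library(duptrp))

ref_seq <- read_fasta("results/reference.fa")
ir <- find_inverted_repeats(ref_seq[[1]], min_arm = 5000,
                            max_spacer = 20000)
write_tsv(ir, "results/inverted_repeats.tsv")
message("inverted repeats detected:")
print(ir)

sites <- read_tsv("results/cis_morphism_sites.tsv")
obs <- read_tsv("results/longread_site_observations.tsv")
res <- phase_breakpoint(obs, sites)
write_phasing_json(res, "results/phasing_result.json")
print(res)
if (res$called) {
  message(sprintf(
    "proximal breakpoint localized to the %d bp inter-site interval (%d-%d)",
    diff(res$breakpoint_interval), res$breakpoint_interval["start"],
    res$breakpoint_interval["end"]))
}
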