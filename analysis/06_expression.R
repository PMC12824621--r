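#!/usr/bin/env Rscript
# Dosage-effect expression analysis: housekeeping-normalized relative
# expression, fold above the cohort mean and cohort z-score for the index
# sample, against the naive CN/2 dosage expectation.

suppressPackageStartupMessages(library(duptrp))

tpm_tab <- read_tsv("results/expression_tpm.tsv")
tpm <- as.matrix(tpm_tab[, -1])
rownames(tpm) <- tpm_tab$gene

res <- expression_outliers(tpm, hk_gene = "GAPDH", index_sample = "INDEX")
res <- res[order(-res$Z), ]
write_tsv(res, "results/expression_outliers.tsv")
message("per-gene outlier scores for the index sample (GAPDH-normalized):")
print(res, digits = 3)

top <- res[1, ]
message(sprintf(
  "top outlier: %s, FC %.2f above the cohort mean, Z = %.1f (outlier bar: Z > 4)",
  top$gene, top$FC, top$Z))
message(sprintf(
  "naive dosage expectation for the constitutional triplication (CN 4): FC %.1f",
  expected_dosage_fc(4)))
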