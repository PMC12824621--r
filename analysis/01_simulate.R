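#!/usr/bin/env Rscript
# Generate the synthetic study locus and every evidence layer with known
# truth: a palindrome-flanked reference, an inverted duplication-triplication
# allele, binned depth, junction read pairs, long-read cis-morphism
# observations, an expression cohort, and a population CNV table.

suppressPackageStartupMessages(library(duptrp))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1, proximal_in_palindrome = TRUE)
ref <- build_reference(cfg)
tr <- apply_architecture(ref, "DUPTRP_1")

message("locus: ", length(ref$seq), " bp; planted architecture ",
        tr$architecture_id, "; breakpoints ",
        paste(tr$breakpoints, collapse = ", "))

write_fasta(ref$seq, "results/reference.fa")
write_fasta(stats::setNames(paste(tr$haplotype, collapse = ""),
                            "rearranged_allele"),
            "results/rearranged_allele.fa")
write_bed(ref$layout, "results/layout.bed")
write_tsv(ref$sites, "results/cis_morphism_sites.tsv")
write_tsv(tr$truth_cn_profile, "results/truth_cn_profile.tsv")
write_tsv(tr$truth_junctions, "results/truth_junctions.tsv")

write_depth_tsv(simulate_depth(tr), "results/depth_bins.tsv")
write_bedpe(simulate_junction_evidence(tr), "results/junctions.bedpe")

lr <- simulate_long_reads(ref, tr)
write_tsv(lr$observations, "results/longread_site_observations.tsv")

exp_sim <- simulate_expression(cohort_n = cfg$expression_cohort_n,
                               dosage_fc = cfg$dosage_fc,
                               cv = cfg$expression_cv, seed = cfg$seed)
tpm <- data.frame(gene = rownames(exp_sim$tpm), exp_sim$tpm,
                  check.names = FALSE)
write_tsv(tpm, "results/expression_tpm.tsv")

cnv <- simulate_population_cnv(n_samples = 500000, n_dup = 19,
                               target_interval = c(2503226, 2529370),
                               seed = cfg$seed)
write_tsv(cnv, "results/population_cnv.tsv")

message("evidence written under results/: depth (",
        nrow(read_depth_tsv("results/depth_bins.tsv")), " bins), ",
        nrow(lr$observations), " site observations, ",
        ncol(exp_sim$tpm), " expression samples, ",
        nrow(cnv), " population CNV calls")
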