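# duptrp

Reconstruction of palindrome-mediated **DUP-TRP/INV-DUP** structural
variants — a triplicated, usually inverted segment embedded within a
duplication — from the evidence clinical genomics actually produces:
binned read depth, discordant/split read pairs, long reads over a
near-identical inverted-repeat (palindrome) pair, cohort CNV tables and
expression matrices. It is written for analysts characterising complex
copy-number gains at loci like 16p13.3, where the rearrangement sits next
to a large palindrome, the proximal breakpoint is unmappable, and the
clinically decisive question is how many copies of a dosage-sensitive gene
sit on the rearranged allele.

The package pairs every inference step with a synthetic-data generator
that plants a known truth, so each claim the pipeline makes is testable.

## The model

The rearranged allele is modelled as three reference runs

```
[0, d1]  +  revcomp([p2, d2])  +  [p1, L]
```

with proximal breakpoints `{p1, p2}` and distal breakpoints `{d1, d2}`.
Read depth constrains total copy number (2–3–4–3–2 across the locus,
i.e. allele multiplicities m = CN − 1 = 1,2,3,2,1 assuming one intact
homolog); junction evidence contributes a tail-to-tail (−/−) edge at the
distal boundary pair and a head-to-head (+/+) edge at the proximal pair.
Exhaustive traversal of the resulting breakpoint graph under these
constraints yields **every** linear architecture consistent with the
evidence — exactly four for this rearrangement class, differing only in
the span of the central inverted copy, which short reads cannot
distinguish. Auxiliary estimators include:

- Viterbi copy-number segmentation with Poisson emissions
  (mean `cn/2 · b`), a uniform transition penalty (default ln 10⁴), and
  iterative baseline refinement;
- mosaic fraction `f = 2(r − 1)/k` from a segment copy ratio `r` with
  extra allele multiplicity `k` (1 dup, 2 trp), with a Poisson-propagated
  95% CI;
- cis-morphism phasing: reads spanning two paralog-distinguishing sites
  inside the palindrome arms localise an otherwise unmappable proximal
  breakpoint to the inter-site interval when they carry a chimeric allele
  pattern;
- cohort minimal region of overlap, interval sizes, population CNV
  screening (DUP ratio ∈ [1.15, 1.75), TRIP ≥ 1.75);
- housekeeping-normalised expression fold-change and cohort z-score
  against the naive dosage expectation FC = CN/2.

## Worked example

```r
library(duptrp)

cfg  <- sim_config(seed = 1)                    # 244 kb locus, 36x depth
ref  <- build_reference(cfg)                    # palindrome + dup/trp/dup
tr   <- apply_architecture(ref, "DUPTRP_1")     # plant the rearrangement

segs  <- segment_cn(simulate_depth(tr), baseline_strategy = "flank_median")
segs$cn
#> [1] 2 3 4 3 2

calls <- cluster_junctions(simulate_junction_evidence(tr))
calls[, c("pos1", "strand1", "pos2", "strand2", "jclass")]
#>     pos1 strand1   pos2 strand2        jclass
#> 1  93992       + 124000       + INV_HEAD_HEAD
#> 2 164013       - 193993       - INV_TAIL_TAIL

part  <- partition_segments(segs, calls, tol = 5 * cfg$bin_size)
walks <- enumerate_architectures(part)
length(walks)
#> [1] 4
sapply(walks, format_walk)
#> [1] "s1 s2 s3 s4 s3- s2 s3 s4 s5"   "s1 s2 s3 s4 s3- s2- s3 s4 s5"
#> [3] "s1 s2 s3 s4- s3- s2 s3 s4 s5"  "s1 s2 s3 s4- s3- s2- s3 s4 s5"

gene <- data.frame(name = "geneA", start = 130000, end = 140000)  # in trp
sapply(walks, function(w) gene_consequences(w, part, gene)$copies)
#> [1] 3 3 3 3
```

Five copy-number segments recover the planted 2–3–4–3–2 profile; the
twenty jittered read pairs per junction collapse to the two true junction
calls; the breakpoint graph admits exactly four architectures (the four
renderings differ in which segments are traversed inverted, `s3-` etc.);
and a gene inside the triplicated segment carries three copies on the
rearranged allele in every one of them — the dosage conclusion is robust
to the structural ambiguity.

The numbered scripts under `analysis/` run the same workflow as a
narrative (simulate → segment → enumerate → phase → cohort → expression),
writing tables under `results/`. For instance `analysis/04_phase_palindrome.R`
detects the planted 20 kb / 99.8%-identity arm pair from sequence alone and
phases the proximal breakpoint into the 4,200 bp inter-site interval, and
`analysis/05_cohort_screen.R` prints the 26.1 kb minimal region of overlap
(g.2503226–2529370) and recovers the 19 planted population duplications
with no triplications.

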