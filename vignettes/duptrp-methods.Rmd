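---
title: "Resolving inverted duplication-triplications: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving inverted duplication-triplications: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duptrp)
```

## The rearrangement and its evidence

A DUP-TRP/INV-DUP is a complex structural variant in which a triplicated
segment, usually inverted, is embedded within a duplication. On read depth it
appears as a stepped total copy-number profile 2-3-4-3-2; in discordant
read pairs it appears as two inverted junctions, a tail-to-tail (-/-)
junction at the distal end and a head-to-head (+/+) junction at the proximal
end. Such events recur next to large genomic palindromes (inverted-repeat
pairs), whose near-identical arms both promote the rearrangement and defeat
read mapping around the proximal breakpoint.

This package models the rearranged allele as three reference runs,

\[
  [0, d_1] \;+\; \overline{[p_2, d_2]} \;+\; [p_1, L],
\]

where the overline denotes reverse complement, \(\{p_1, p_2\}\) are the two
proximal breakpoint positions and \(\{d_1, d_2\}\) the two distal ones. The
observable evidence constrains only the *sets*: every assignment of
\((p_1, p_2)\) and \((d_1, d_2)\) produces the same junction breakends and
the same depth profile. The \(2 \times 2\) assignments are exactly the four
structures that short-read data cannot distinguish, and they differ in the
span of the central inverted copy. `enumerate_architectures()` derives them
from the evidence rather than assuming them: it performs an exhaustive
depth-first traversal of the breakpoint graph (segment extremities,
reference adjacencies, junction edges) subject to three constraints:

* each segment is traversed exactly \(m\) times, where \(m = \mathrm{CN} - 1\)
  under the intact-homolog assumption (one normal homolog contributes one
  copy everywhere; all pedigree data for these events are consistent with
  this),
* every consolidated junction call is explained by at least one traversed
  junction edge (for a breakend with ambiguous placements inside a repeat
  pair, at least one placement),
* orientation flips occur only across inverted junction edges.

A walk and its full reverse complement describe the same molecule; walks are
reported anchored at the left flank in forward orientation and deduplicated
by the lexicographically smaller of the two renderings, so the pair counts
once. `max_walks` (default 64) guards against adversarial inputs; the
genuine fixtures yield at most four.

### Gene consequences and their limits

`gene_consequences()` decomposes a walk into maximal reference-contiguous
runs. A gene's copy number on the rearranged allele is the number of runs
containing it entirely; a gene is *disrupted* when some run terminates
strictly inside it, i.e. a junction breakend falls within the gene. One
consequence is worth stating explicitly because it is easy to get wrong: for
evidence-equivalent walks the number of severed copies at any junction
breakend is fixed by the junction usage counts, which are identical across
the walks. A gene straddling a used breakend is therefore disrupted in
*every* enumerated architecture, and a gene contained in a segment in none;
no per-gene disruption pattern can separate the four structures. What does
differ between them is the span of the central inverted copy, and hence
which sequence is carried in inverted orientation -- the property that
longer reads or optical maps can resolve.

## Copy-number segmentation

`segment_cn()` decodes the maximum a-posteriori integer copy-number path
(states 0-6) under per-bin Poisson emissions with mean
\(\mathrm{cn}/2 \times b\), where \(b\) is the diploid mean bin count, and a
uniform transition penalty (default \(\ln 10^4 \approx 9.2\) nats) per state
change. Ties break toward the lower copy number, making output
deterministic. The state cap at total CN 6 covers the five-copy alleles
reported for this locus class while keeping the Viterbi recursion bounded.

Two practical refinements matter more than the decoder itself:

* **Baseline refinement.** A baseline estimated from a few dozen flank bins
  carries 2-3% error, which is enough to bias the position of a 3-vs-4 step
  by several bins. After each decoding the baseline is re-estimated as
  \(2 \sum x_i / \sum \mathrm{cn}_i\) (the Poisson MLE over all bins) and
  decoding repeats until the path is stable (at most 5 rounds).
* **Short-segment absorption.** Segments shorter than 3 bins are absorbed
  into the neighbour with the closer mean ratio. This suppresses the
  single-bin flicker that low-mapping-quality bins produce inside repeats;
  genuinely masked bins can also be excluded via a mask BED, in which case
  they contribute no emission term.

Even with an exact baseline, the precision of a recovered step position is
limited by information, not implementation: at 36 expected counts per
diploid bin, the exact maximum-likelihood changepoint estimator misses a
3-vs-4 boundary by two or more bins in roughly 8% of draws (and a 2-vs-3
boundary in about 4%). Recovery of all four steps of a 2-3-4-3-2 profile
within one bin therefore plateaus near 80% of replicates at this depth; the
package reports what the data support rather than sharpening it post hoc.

### Mosaic fraction

For a gain of extra multiplicity \(k\) (1 in dup-only, 2 in triplicated
regions) carried by a fraction \(f\) of cells, the expected copy ratio is
\(r = 1 + fk/2\), so `estimate_mosaic_fraction()` inverts
\(f = 2(r-1)/k\), clips to \([0, 1]\), and propagates the standard error of
the segment mean under Poisson counts into a 95% interval. Simulated depth
uses the same model: bin means are \(h \,(2 + f\,(T - 2))\) with \(h\) the
haploid per-bin depth and \(T\) the constitutional total CN, so \(f = 1\)
recovers the constitutional ratios 1.5 (dup) and 2.0 (trp), and
\(f = 0.35\) gives 1.175 and 1.35. With a 1,000-bin segment at 36x the
estimator recovers a planted \(f = 0.35\) within \(\pm 0.05\) essentially
always; the generator plants \(f\) directly rather than reproducing any
particular published parent, whose exact estimation procedure is not public.

## Junction evidence

BEDPE strand pairs map to junction classes by the read-pair convention
adopted throughout: `(+,+)` head-to-head inversion, `(-,-)` tail-to-tail
inversion, `(+,-)` deletion-like, `(-,+)` tandem-duplication-like, with
breakends ordered `a <= b`. The simulator emits strands through the same
table, so the classes round-trip by construction and the distal junction of
an inverted duplication-triplication is always supported by (-,-) pairs.
`cluster_junctions()` consolidates rows per strand pair by single-linkage
chaining within `max_cluster_distance` (default 500 bp) and reports median
positions; calls need `min_support` (default 3) rows. The defaults reflect
the scale of real support: a handful of pairs per junction in short-read
data, and a long-read case supported by only four reads that was
deliberately treated as insufficient.

## Palindrome detection and cis-morphism phasing

`find_inverted_repeats()` finds arm pairs by exact k-mer seeding between the
sequence and its reverse complement, chaining seeds along anti-diagonals
(the invariant \(i + j\) of an inverted match) and extending ends with an
ungapped X-drop scheme in which a mismatch costs \((1-f)/f\) matches, so
extension pays only while local identity stays above \(1-f\)
(`max_mismatch_fraction`, default 2%). Arms are clamped at the anti-diagonal
midpoint so they never cross, and overlapping candidates are resolved
longest-first. Desk-scale sequences (under 1 Mb) need no suffix-array
machinery; detection of a 20 kb, 99.8%-identity planted pair takes about two
seconds. Boundary placement is accurate to a few bases, not exact: a stray
matching base just outside an arm can extend it by 1-2 positions.

Phasing uses the two paralog-distinguishing cis-morphism sites carried by
the arms (4.2 kb apart at the defaults). A read spanning both sites through
an intact arm reports that arm's allele twice; a read crossing a proximal
junction that falls *between* the sites inside an arm reports one allele
from each arm. `phase_breakpoint()` tabulates the four patterns over
informative reads and calls a breakpoint when the dominant chimeric pattern
has at least `min_informative_reads` (default 5, deliberately just above the
four-read case) and at least `confidence_threshold` (default 0.8) of all
chimeric-pattern reads. Read origin is unobservable, so the confidence
denominator is the chimeric subset -- the reads that cannot derive from an
intact arm -- rather than a notional "rearranged haplotype partition".
Observations matching neither arm allele are discarded as sequencing error;
reads observing one site twice with conflicting alleles (possible only when
a read spans most of the repeat) are dropped as ambiguous. The returned
interval is the open inter-site interval on arm 1; it contains the planted
breakpoint whenever a call is made, and with 1% per-site error the
false-call rate on reference-only reads is below 1%.

## Cohort and expression analytics

Printed genomic intervals are 1-based inclusive and converted on input;
everything internal is 0-based half-open (BED convention).
`minimal_region_of_overlap()` is a plain interval intersection --
order-invariant, associative, monotonically shrinking -- with an
`approximate` flag propagated from flagged inputs. `interval_length_kb()`
uses \((\mathrm{end} - \mathrm{start} + 1)/1000\); inclusive and exclusive
arithmetic agree at the precision such intervals are printed with.
`screen_population()` keeps calls of at least `min_size` (default 10 kb)
overlapping the target by at least 1 bp -- the overlap criterion is
deliberately minimal and configurable, since no overlap fraction is implied
by "overlapping the gene" -- and classifies copy ratios with DUP in
\([1.15, 1.75)\) and TRIP at \(\ge 1.75\), bands centred on the
constitutional expectations 1.5 and 2.0.

Expression scoring is intentionally simple: divide by a housekeeping gene
per sample, compare the index sample with the cohort *excluding itself*
(self-contamination matters at small \(n\)), and report fold-above-mean and
the plain cohort z-score (optionally on log2 values). Genes below a cohort
mean TPM threshold can be masked; ratios of near-zero values are unstable.
This is not an autoencoder-controlled outlier model and is not meant to
reproduce statistics computed by one; under the naive proportional dosage
model `expected_dosage_fc()` returns \(\mathrm{CN}/2\), and the planted
2-fold effect yields z-scores far above the conventional outlier bar of 4.
A single index measurement carries \(\mathrm{cv}\sqrt{2}\approx 14\%\)
ratio noise at \(\mathrm{cv} = 0.1\), so fold-change recovery to
\(\pm 0.1\) is a property of the Monte-Carlo mean over seeds, not of any
single draw.

## What the generator emulates, and what it does not

`build_reference()` plants, on a random sequence, an inverted-repeat pair
(default 20 kb arms at 99.8% identity, 4 kb spacer) carrying two
cis-morphism sites, followed by dup/trp/dup segments (30/40/30 kb) between
50 kb flanks; depth is Poisson (optionally negative binomial) at a haploid
18 counts per 500 bp bin, junction pairs are jittered +/-50 bp, long reads
average 20 kb with 800 reads (about 30x across the two haplotypes), and the
expression cohort has 100 controls at cv 0.1. These desk-scale defaults
keep every Monte-Carlo in the test suite within seconds while preserving
the statistical contrasts that matter (3-vs-4 depth steps, chimeric-read
counts near their thresholds).

Two geometries are supported for the proximal breakpoints of DUP-TRP
architectures. By default they sit at the `dup_left`/`trp` segment
boundaries, so the named segments carry total CN (3, 4, 3) exactly -- the
clean bookkeeping used for segmentation and enumeration fixtures. With
`proximal_in_palindrome = TRUE` they sit at paralogous positions inside the
two arms, midway between the cis-morphism sites -- the palindrome-mediated
geometry that actually produces chimeric-arm long reads, used for phasing.
A single layout cannot satisfy both descriptions at once, which is why the
switch exists.

The generator does not emulate: base-level sequencing error profiles or
FASTQ/BAM output (allele observations are tabulated directly; per-site
error is injected at 1%), GC or mappability bias, alignment artefacts
beyond the masking hook, multi-chromosome events, or the annotation and
cohort-normalisation complexities of real expression data. Passing tests
therefore demonstrate correctness of the inference on data whose noise
structure is known, not performance on access-controlled patient data; the
cohort-scale published statistics (autoencoder z-scores, biobank screens,
parental mosaic fractions) are validated here only against planted
synthetic truth.

## Problem sizes used by the test suite

Unit tests run on a miniature locus (5 kb flanks, 2 kb arms, 100 bp bins).
Property-style checks use: 100 seeded replicates for segmentation-step
recovery and for mosaic-fraction recovery (1,000-bin segments), 100
replicates each for phasing recovery and false-positive rate (800 reads per
replicate), 25 random instances against the exhaustive Viterbi oracle
(paths enumerated completely at up to 9 bins x 4 states), 12 random
instances plus the four-structure fixture against the brute-force walk
enumeration oracle, and 20 seeds for expression fold-change recovery. The
full suite completes in about a minute on one core.
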