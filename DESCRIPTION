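Package: duptrp
Title: Resolving Palindrome-Mediated Inverted Duplication-Triplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of complex DUP-TRP/INV-DUP structural variants from
    short- and long-read sequencing evidence. Provides read-depth copy-number
    segmentation with mosaic-fraction estimation, breakpoint-junction
    classification and clustering, exhaustive enumeration of rearranged-allele
    architectures over a breakpoint graph with per-gene dosage consequences,
    inverted-repeat (palindrome) detection with cis-morphism breakpoint phasing,
    cohort minimal-region-of-overlap and population CNV screening, and
    housekeeping-normalised expression dosage-outlier scoring. A synthetic-data
    generator with known truth emulates the full evidence chain for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
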