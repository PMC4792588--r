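Package: arvscan
Title: Detection and Quantification of Androgen Receptor Splice Variants
    from Locus-Restricted RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies C-terminally truncated androgen receptor
    (AR) splice variants, notably AR-V7, from locus-restricted RNA-seq
    alignments. Splice gaps are parsed from SAM CIGAR strings, filtered on
    mapping quality and junction overhang, matched exactly against a curated
    exon/junction catalog, and counted as junction-spanning read evidence for
    cryptic-exon and exon-skipping events. Provides normalized variant
    ratios (target-junction reads scaled by the summed first-junction
    reads), cohort positivity summaries, count correlations, a qPCR arm
    (standard-curve absolute quantification, Cq-cutoff positivity, variant
    fractions, delta-delta-Cq fold changes), and a seeded read simulator
    with exact junction-level ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    Rsamtools,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
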