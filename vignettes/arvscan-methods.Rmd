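---
title: "Methods: junction-spanning detection of AR splice variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-spanning detection of AR splice variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arvscan)
```

## The detection model

`arvscan` treats variant detection as an exact-matching problem over a
curated splice model. A locus catalog declares exons (canonical,
alternative-first such as AR exon 1a, and cryptic such as CE1/CE3/CE4/CE5),
junctions between them, and the variant transcripts each non-canonical
junction diagnoses. A junction's identity is its genomic gap — the
0-based half-open interval from the upstream exon's end to the
downstream exon's start — and an aligned read supports a junction if
one of its CIGAR `N` gaps equals that interval exactly.

Only gapped reads count. Exonic coverage over a cryptic exon is never
taken as variant evidence, because unprocessed pre-mRNA and genomic DNA
contamination produce exactly that signal; a splice gap, by contrast,
can only come from a processed transcript. The cost of this choice is
sensitivity: at read length $L$ and minimum anchor $m$, only
$L - 2m + 1$ start positions on a transcript produce a qualifying read
over a given junction, so shallow samples can carry a variant
undetected.

Assumptions worth stating explicitly:

* **Exact junction boundaries.** No fuzzy matching window: a gap one
  base off matches nothing. This presumes alignments from a
  splice-aware pipeline with correct junction placement.
* **Coordinate-only matching.** Strand is catalog metadata; read
  strand flags are ignored, appropriate for unstranded libraries.
* **Mate independence.** Paired mates, when present, are counted as
  independent observations; there is no fragment-level deduplication.
  Counts are therefore evidence scores, not fragment estimates.

## Filters and their defaults

| parameter | default | meaning |
|---|---|---|
| `min_overhang` | 6 bp | minimum reference-aligned anchor on *each* side of a gap; the boundary is kept (6 passes, 5 fails) |
| `drop_mapq0` | TRUE | discard mapping-quality-0 alignments only — not a general threshold |
| `drop_secondary` | TRUE | discard secondary/supplementary records |
| `min_reads` | 1 | spanning reads needed to call an event detected |
| `min_ref_reads` | 10 | reference-junction reads needed for a sample to enter ratio summaries |

The overhang is defined as the number of M/=/X bases between the gap
and the nearest `N` operation or read terminus on that side; insertions
and deletions contribute nothing. The filter applies **per gap**, not
per read: a read with one poorly anchored and one well-anchored gap
contributes only the latter. This is the natural reading of an anchor
filter as junction-evidence quality control; applying it per read would
discard valid evidence for no gain.

## Normalization

No splice junction is unique to the full-length transcript, so the
AR-V7 signal (exon 3-CE3 reads) is scaled by the *sum* of the
first-junction reads (exon 1-2 plus exon 1a-2), which every isoform
must cross. Sum — not maximum or either/or — because the two first
junctions partition the same transcription flow between alternative
first exons. The ≥ 10-read denominator floor guards against ratio
inflation in low-expressing samples and applies only to ratio
reporting; detection stays at the one-read rule. Ratios in excluded
samples are still computed (when the denominator is nonzero) and
flagged, so the filter is auditable rather than silent.

Cohort percentages are rounded **half-up** to one decimal
(`round_half_up()`); base R's round-half-to-even would print some
boundary percentages one tick low.

## qPCR arm

Standard curves are ordinary least squares of Cq on log10 copies;
efficiency is $10^{-1/\text{slope}}$. Absolute copies come from
inverse prediction. Numerical behavior at the edges: fewer than two
distinct dilution levels is a fit error; non-positive copies are an
input error; a missing Cq is an undetected marker and propagates as
`NA` copies rather than an error. Positivity is strict (`Cq < 35`;
Cq = 35 is negative). Fold changes use the classic $2^{-\Delta\Delta
C_q}$ with efficiency fixed at 2 even when a fitted curve suggests
otherwise — the curve-derived efficiency is reported alongside, but
substituting it would silently change the estimand relative to the
standard method. Technical replicates are collapsed by arithmetic mean
Cq before any transform. Copy numbers are per reaction; no per-ng-RNA
normalization is applied because input masses are assay metadata the
package does not see.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws, per sample $i$:

* a locus expression factor $F_i \sim \mathrm{LogNormal}(\mu, \sigma)$
  (defaults $\mu = 0$, $\sigma = 0.5$),
* a read count $N_i \sim \mathrm{Poisson}(d \cdot F_i)$ with mean
  depth $d = 300$ reads over the locus,
* per-read transcript assignment from mixture weights
  $w_t \propto p_t \exp(\beta z_i \cdot \mathbb{1}[t\text{ is variant}])$,
  where $z_i$ is the standardized log locus factor and $\beta = 0.5$
  by default,
* a uniform fragment start along the chosen transcript.

Each read's POS/CIGAR is the exact genomic projection of its transcript
interval through the exon chain, and the generator records the true
spanning count per junction (both anchors ≥ 6 bp). The coupling tilt,
together with the shared locus factor, makes variant-junction counts
rise concordantly with full-length transcription — the qualitative
correlation structure seen in tumor cohorts.

Default mixture: AR-FL 0.85, AR-V7 0.06, AR45 0.04, AR-V1 0.015,
AR-V3 0.015, AR-V9 0.01, AR-V13 0.01 — a full-length-dominated locus
with AR-V7 the most frequent variant, chosen once as domain-plausible
values; no published depth or mixture distributions exist for this
setting, so these defaults are placeholders with the right qualitative
shape, not estimates.

The simulator deliberately omits: sequencing errors that move
alignments (its `base_error_rate` perturbs sequence content only),
positional/GC bias, paired-end structure, indels, multi-mapping
ambiguity and alignment failure. Passing the exactness tests therefore
shows the counting arithmetic is right, not that a real aligner's
output over a repetitive locus would be this clean. The shipped AR
catalog uses synthetic coordinates; analyses of real data require a
user-supplied catalog with genome coordinates, which the same
machinery consumes.

Determinism: every sample draws from its own stream seeded by
$(\text{seed} \cdot 1000003 + i) \bmod (2^{31}-1)$, so cohorts are
reproducible sample-by-sample and byte-identical across runs under R's
default Mersenne-Twister generator.

## Design choices where the design was open

* **Exon 1a acceptor.** The catalog models 1-2 and 1a-2 as different
  donors into the same exon 2 acceptor, the simplest structure
  consistent with an alternative first exon.
* **The 6-9 skipping event** is an ordinary catalog junction between
  exons labeled "6" and "9"; the non-canonical terminal exon 9 is a
  catalog row like any other, keeping biology in data rather than
  code.
* **Events, not variants.** Several variants can share one junction
  (3-CE1 → AR-V1/AR-V2/AR-V4), so reporting resolves to junction
  events with candidate variant sets attached, never to a single
  variant name.
* **Per-sample quantitation** is reported as raw junction counts and
  the normalized ratio only; depth-scaled units (TPM-like) would
  require library-size information the locus-restricted input does
  not carry.
* **Interface.** The exported functions are the primary surface; the
  `inst/cli/arvscan` script is a thin wrapper providing `scan`,
  `summarize`, `simulate` and `qpcr` subcommands for shell use.

## Validation scale

The test suite validates counting exactness on 20 independent cohorts
of 25 samples (read length 100, mean depth 300), cross-checked
read-by-read against a brute-force per-base CIGAR interpreter and
against `GenomicAlignments`; ratio recovery on 30-sample cohorts at
depth 1500 for target fractions 0.01/0.1/0.5; correlation structure on
a 200-sample coupled cohort; and qPCR efficiency recovery at Cq noise
σ = 0.2. These sizes make the binomial error bands tight enough to be
meaningful while keeping the suite quick to run.

## Known limitations

* Exact gap matching cannot tolerate aligner-shifted junction
  boundaries; a tolerance window is deliberately not offered.
* Detection at one read has no error model; with deep cohorts a single
  spurious spanning alignment flips a sample positive. `min_reads`
  exists for sensitivity analyses, but no statistical test of event
  presence is provided.
* The ratio is a junction-read ratio, not an isoform fraction;
  transcript-length effects mean it under- or over-states molar
  variant share depending on read length and transcript structure.
* Single-reference-gene qPCR normalization only; no multi-gene
  geometric-mean scheme, melt-curve QC or plate-effect modeling.
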