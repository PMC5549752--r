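---
title: "Paired DNA/RNA amplicon analysis of cloud water communities: methods and design"
author: "cloudAmplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired DNA/RNA amplicon analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudAmplicon)
```

# The problem

Clouds carry a dilute but diverse microbial community: cells aerosolized
from soils, plants and oceans are scavenged into droplets, where a fraction
of them remains metabolically active. Characterizing that community means
sequencing bulk cloud water in two fractions per sample — rDNA (everyone,
alive, dormant or dead) and rRNA (weighted towards ribosome-rich, hence
potentially active, cells) — and comparing them. Because the habitat is
extremely low-biomass, the analysis must be deliberately conservative:
sequencing artefacts, laboratory contaminants and fraction-specific
inconsistencies can easily rival the real signal.

This package implements that downstream analysis as a reusable, fully
tested pipeline operating on OTU count tables (with an optional read-level
entry point), and a synthetic-data generator that reproduces the
statistical structure the analysis assumes so that every stage can be
validated against known ground truth.

# Pipeline and models

## Read cleaning

Reads are cleaned by four rules applied in a fixed order — forward primer,
reverse primer (reverse complement at the 3' end), post-trim length,
ambiguous bases, mean PHRED quality — with each rejected read attributed to
the first rule it fails, so reports are reproducible and conserve counts.
Two decisions here were genuinely open:

* **"Quality below 25"** is interpreted as *mean* read PHRED < 25. A
  read-level threshold quoted as a single number is conventionally a mean;
  a per-base reading would discard essentially all real data at 25.
* **Length is measured after primer trimming**, since the amplicon insert
  is the biologically meaningful quantity. Primers are matched with zero
  mismatches by default, but degenerate IUPAC positions in the primer are
  never counted as mismatches.

## OTU clustering

A reference implementation of length-sorted greedy centroid clustering:
sequences are processed in decreasing length order (ties: decreasing
abundance, then id — fixed so the partition is deterministic) and each joins
the *first* centroid whose identity reaches the threshold (0.97 for 16S,
0.95 for 18S), else founds a new cluster. First-match (rather than
best-match) assignment mirrors the greedy tool family this emulates; it can
change partitions and is therefore stated here.

Identity is computed by a C++ Needleman–Wunsch with free terminal gaps
(match +1, mismatch −1, gap −1): matched columns divided by internal
alignment columns, so a sequence contained in another has identity 1. The
exact identity dialect of large-scale clustering tools is configurable and
tool-specific; the definition is localized in `pairwiseIdentity()` and
cross-checked in the tests against an independent ends-free alignment
(`Biostrings::pairwiseAlignment`, overlap mode, identical scoring). This is
a desk-scale reference implementation — it is quadratic per pair and linear
in centroids per query, intended for validation and small studies, not for
millions of reads.

## Conservative filtering

Three stages, in the order artefacts → contaminants → phantoms:

1. **Minimum reads** (default 3): an OTU with fewer than 3 reads *in total
   across all fractions of the table* is treated as a sequencing artefact.
   The total-across-dataset scope is the conservative reading of a
   per-dataset artefact threshold.
2. **Decontamination**: any OTU detected (count > 0) in any negative
   control column is removed from all fractions, and control columns are
   dropped. The rule is presence-based by design — no frequency model — and
   a table without controls raises an error unless the caller explicitly
   opts out, so a missing control is never silent.
3. **Phantoms**: an OTU detected in a sample's RNA fraction but not in the
   same sample's DNA fraction is biologically inconsistent under the
   paired design and treated as artefactual. The rule is applied *per
   sample*, by zeroing the RNA counts in the offending sample only: an OTU
   legitimately DNA-backed in another sample keeps its counts there. A
   `scope = "global"` variant (remove the OTU everywhere) is provided,
   since either reading of the rule is defensible. After this stage every
   RNA-positive (OTU, sample) pair has DNA backing, which is exactly the
   precondition that makes all downstream RNA:DNA ratios finite.

The chain sweeps its three stages repeatedly until a fixed point: zeroing
phantom RNA can drop an OTU's total below the artefact threshold, and a
single sweep would leave such OTUs for a second run to remove. Iterating
makes the chain idempotent, which is the property a "conservative filter"
should have: running it twice removes nothing new. The `FilterLedger`
records, per stage, the OTUs removed and reads lost, and satisfies
`reads_in == reads_out + sum(removed)` by construction (validity-checked).

Normalization is to column proportions rather than rarefying: subsampling
discards data, and between-fraction depth differences cancel in the ratios
anyway.

## Diversity and evenness

All statistics are implemented from their closed forms and cross-checked
against vegan in the tests:

* **Shannon H** in natural log. With communities of ~20,000 OTUs, reported
  H values above 9 are only attainable in nats (max ln 20432 ≈ 9.9; log10
  would cap at 4.3), so nats is the base consistent with near-maximal
  diversity in very rich samples.
* **ACE** with the classic rare cutoff of 10; when every rare read is a
  singleton the coverage estimate degenerates (C_ace = 0) and the estimator
  falls back to Chao1.
* **Gini** over observed OTUs only, with the sorted-index sample formula;
  the Lorenz curve is built from the same sorted cumulative sums.
  Unobserved taxa are unknowable and excluded by construction.
* **Coverage** is defined as observed/ACE richness — the definition under
  which the packaged per-sample summaries reproduce the headline 72%–98%
  range. Good's coverage (1 − F₁/N) is provided as a secondary measure.
* **Rarefaction**: the exact hypergeometric expectation is computed in
  log-gamma space (`lchoose`), so arbitrary depths do not overflow;
  subsampled rarefaction is a true multivariate hypergeometric draw
  (without replacement) with an explicit seed argument — global RNG state
  is never touched.

## Activity

Ratios are computed on column-normalized proportions, at OTU level
(`otuRnaDnaRatios()`) or aggregated to a taxonomic rank
(`activityTable()`; genus for prokaryotes, order for eukaryotes — the ranks
at which such communities are conventionally summarized). Banding uses the
0.1 / 1 / 10 anchors; a ratio of exactly 1 counts as active (the boundary
is ambiguous in prose conventions; inclusive was chosen and is stated).
Zero RNA gives ratio 0; zero DNA with positive RNA is an error — such
entries must have been removed by the phantom filter, and a leak indicates
a pipeline misuse.

Top-taxon selection ranks taxa within each sample by decreasing DNA
relative abundance (rank 1 = most abundant; absent taxa get rank n+1),
averages ranks across samples, and takes the best n (default 20), ties
broken by total abundance then name. The ranking fraction is a free choice;
`rankBy = "rna"` and `"mean"` are provided as alternatives.

No 16S copy-number or rRNA-operon correction is applied: ratios are
comparative proxies, not absolute activities, and copy-number variation
(especially in eukaryotes) is a stated caveat of the method, not something
this package attempts to model away.

# The synthetic generator

`generateCommunity()` emulates the data structure the analysis assumes:

* **Heavy-tailed abundances**: per sample, base abundances are log-normal
  (mean 0, σ default 2) — at realistic richness this yields Gini
  coefficients around 0.8–0.95, matching the highly uneven communities such
  surveys report.
* **Sequencing**: DNA and RNA columns are multinomial draws of the
  configured depths (so column sums are exact).
* **Activity**: a designated active fraction receives log-uniform RNA
  multipliers in (3, 10); a designated inactive fraction in (0.1, 1/3); the
  remainder is neutral (multiplier 1). Multipliers scale base abundances,
  which are then renormalized — so realized ratios are shrunk by the
  community-wide scale factor, as in real compositional data.
* **Rare-ratio inflation** (off by default): multiplier scaled by
  1 + inflation/percentile of ascending abundance, reproducing
  qualitatively the tendency of low-abundance taxa to show elevated ratios.
* **Contaminants**: extra OTUs with Poisson(+1) counts in a control DNA
  column and moderate-to-high abundance in the samples — deliberately the
  hard case for presence-based removal.
* **Phantoms**: extra OTUs with RNA-only abundance.
* **Determinism**: every draw comes from one seeded generator; equal seeds
  give byte-identical output.

What it does *not* emulate: PCR and chimera error models, realistic
per-base quality profiles, phylogenetically structured taxonomies, or
between-sample correlation of abundances (each sample's base abundances
are independent draws). Passing tests on this generator therefore validate
the pipeline's logic and statistics, not its robustness to amplification
artefacts — chimera detection is explicitly out of scope and assumed done
upstream.

## The recovery experiment

The acceptance-level experiment asks: with 500 OTUs, 50,000 reads per
fraction, active multipliers ≥ 3 and inactive ≤ 1/3, does the ratio ≥ 1
rule recover the designated active set with recall and precision ≥ 0.9?
Two design choices were fixed a priori:

* **Bimodal activity** (inactive fraction = 0.9, no neutral OTUs): the
  experiment probes the classification rule, and a neutral OTU's true
  post-normalization ratio sits just below 1 — near the decision boundary —
  so a community dominated by neutral taxa measures boundary noise, not
  rule quality. The worked example in the README shows exactly this
  contrast: with 70% neutral OTUs, recall stays 1.0 but precision drops to
  ~0.7.
* **Scoring over observable OTUs**: recall and precision are computed over
  OTUs present after the filter chain. Under a σ = 2 log-normal, roughly
  15% of OTUs have expected counts below detectability at this depth;
  whether such an OTU is "recovered" is a property of sequencing depth,
  not of the classification rule being tested.

# Numerical choices and degenerate inputs

* Ties in clustering (equal length) break by abundance then id; ties in
  top-taxon ranking by total abundance then name. All orderings are total,
  so results are deterministic.
* All-zero count vectors are errors for diversity statistics (no silent
  NaN); zero-total columns are errors for normalization; `minReads < 1`,
  negative ratios, unknown ranks, depths exceeding totals all raise typed
  errors naming the offending quantity.
* Air-concentration reporting rounds to 2 significant figures at ≥ 100 and
  1 below — the convention that reproduces conventional reporting of such
  measurements (268 → 270, 7.6 → 8).
* Empty tables, empty FASTQ files and empty cluster sets are all valid and
  round-trip correctly.

# Problem sizes

The test suite runs the generator at 40–500 OTUs and depths of 2×10³–10⁵
reads per fraction, clustering at ≤ 50 sequences of ~100–250 bp against a
brute-force oracle, and Monte-Carlo rarefaction with 10⁴ draws — sizes
chosen so the full suite completes in well under a minute per module while
still exercising every statistical property at meaningful scale. The
full-scale studies this design mirrors involve ~10⁷ reads and external
clustering/annotation pipelines; reproducing those is a non-goal, and the
clustering module is explicitly a reference implementation.

# Known limitations

* Greedy clustering is O(n · centroids) with quadratic pairwise alignment:
  practical to ~10⁴ sequences.
* Presence-based decontamination removes genuinely shared taxa that enter
  controls by cross-contamination; that is the price of the conservative
  design, accepted deliberately.
* Per-sample phantom zeroing (rather than global removal) keeps DNA-backed
  evidence in other samples but means an OTU's RNA column can be zero in
  one sample and positive in another by filtering, not biology; the
  `scope` flag exposes the alternative.
* RNA:DNA ratios are relative within a sample and fraction pair; they are
  not growth rates and are not comparable across taxa with very different
  ribosome or operon-copy regimes.
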