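# cloudAmplicon

Downstream analysis of **paired DNA/RNA (rDNA / rRNA) amplicon surveys** of
low-biomass aerial habitats — cloud water in particular. Microbial cells
scavenged into cloud droplets can be sampled in bulk water, sequenced in both
the DNA (total community) and RNA (potentially active community) fractions,
and compared: the ratio of a taxon's relative abundance in the RNA fraction
to its relative abundance in the DNA fraction (the **RNA:DNA ratio**) is a
classic proxy for relative metabolic activity. The package is written for
microbial ecologists working with such paired 16S/18S data sets, and for
anyone who needs a tested, self-contained reference implementation of the
surrounding machinery.

It covers, end to end:

* **Read cleaning** — length (< 200 bp), forward/reverse primer mismatch
  (IUPAC-aware), ambiguous bases, mean PHRED quality < 25; first-failing-rule
  reporting.
* **Greedy centroid OTU clustering** at a configurable identity threshold
  (0.97 prokaryotes / 0.95 eukaryotes), length-sorted, with an ends-free
  pairwise identity kernel in C++.
* **Conservative community filtering** — artefacts (OTUs with < 3 reads in
  total), contaminants (OTUs detected in negative controls, presence-based),
  and *phantom* OTUs (detected in a sample's RNA fraction but absent from
  the same sample's DNA fraction), with a read-conserving `FilterLedger`.
* **Diversity and evenness** from closed forms — Shannon
  `H = −Σ pᵢ ln pᵢ` (nats), the ACE richness estimator
  `S_abund + S_rare/C_ace + (F₁/C_ace)·γ²` (rare cutoff 10, Chao1 fallback),
  Gini coefficient / Lorenz curves, coverage = observed/ACE, and exact
  (hypergeometric, `E[S_m] = Σᵢ 1 − C(N−Nᵢ, m)/C(N, m)`) plus subsampled
  rarefaction.
* **Activity analysis** — RNA:DNA ratios per OTU and per taxon on
  column-normalized proportions, banding at 0.1 / 1 / 10 (ratio ≥ 1 =
  potentially active), top-n taxa by average abundance rank across samples.
* **Between-sample structure** — shared-OTU (Venn) partitions with per-region
  read fractions, Bray–Curtis similarity, and the conversion from cells per
  mL of cloud water to cells per m³ of cloudy air
  (`conc × water_volume / air_volume`).
* A **seeded synthetic-community generator** (log-normal abundances,
  multinomial sequencing, designated active/inactive sets, contaminants,
  phantoms, optional read-level FASTQ) with full ground truth, so every stage
  is testable without any external download.

The central container is `OtuExperiment`, an S4 class extending
`SummarizedExperiment` (rows = OTUs, columns = sample fractions, assay =
counts, taxonomy in `rowData`).

## Worked example

```r
library(cloudAmplicon)

cfg <- syntheticConfig(nOtus = 200L, depthDna = 2e4, depthRna = 2e4, seed = 11L)
g   <- generateCommunity(cfg)
fc  <- runFilterChain(g$table)
fc$ledger
#> FilterLedger: 120103 reads in, 117118 reads out
#>           stage otus_removed reads_removed
#> 1     min_count            0             0
#> 2 decontaminate            5          1884
#> 3       phantom           10          1101

diversityReport(fc$table)[, c("label", "observed", "shannon_h", "ace",
                              "gini", "coverage")]
#>        label observed shannon_h ace  gini coverage
#> 1 cloud1_DNA      181      3.54 184 0.819    0.983
#> 2 cloud1_RNA      159      2.44 165 0.891    0.965
#> ...
```

All 5 designed contaminants and all 10 designed phantoms are caught by their
stages; the diversity report gives per-fraction observed/ACE richness,
Shannon H in nats, Gini unevenness and coverage (observed/ACE). The activity
screen then bands every OTU's RNA:DNA ratio:

```r
scr <- otuRnaDnaRatios(fc$table)
table(scr$band)
#>     zero   lt_0.1 0.1_to_1  1_to_10    gt_10
#>        0       11      160       29        0

recoveryScores(scr$otu_id[scr$active], g$truth$active_set, scr$otu_id)
#>  recall precision ...
#>    1.00      0.69
```

All 20 truly active OTUs (RNA multiplier 3–10) are recovered. Precision is
moderate *under this default configuration* because 70% of the community is
neutral (multiplier 1) and sits just below the ratio-1 boundary after
renormalization, so sampling noise pushes some across; when activity is
bimodal (every non-active OTU truly inactive), precision also exceeds 0.9 —
see the methods vignette.

Field-data conversions use the packaged sample characteristics:

```r
formatAirConcentration(cellsPerAirVolume(8.67e2, 94, 304))
#> [1] 270   # eukaryotic cells per m3 of cloudy air, most concentrated sample
```

## Layout

* `R/` — implementation (S4 classes, one file per analysis stage)
* `src/` — C++ identity kernel (ends-free Needleman–Wunsch)
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/cloud-amplicon-activity.Rmd` — methods vignette
* `inst/extdata/` — packaged per-sample summary tables (plain TSV)
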