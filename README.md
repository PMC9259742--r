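# scatdiet

Scat DNA metabarcoding diet analysis for carnivores: a tested, reusable R
pipeline from amplicon reads to regional diet statistics.

Field studies of elusive carnivores collect scats, identify the depositing
species with a mammal-generic marker, identify food items with a prey
marker amplified alongside a predator-blocking primer, separate wild from
domestic sheep/goat prey with a mitochondrial D-loop marker, and assign
scats to individual animals with replicated microsatellite genotyping.
`scatdiet` implements the computational side of that design end to end:

* **Read processing** — paired-read merging by exhaustive ungapped overlap
  search, expected-error (`maxee`) and amplicon-length filtering,
  exact-sequence dereplication to zero-radius OTUs with singleton removal.
* **Taxonomic binning** — query-cover and geographic-presence filtering of
  alignment hit tables, then LCA-style binning with inclusive per-rank
  percent-identity thresholds (species/genus/family/above-family, default
  99) under unanimity semantics, plus a threshold-selection diagnostic from
  labelled within/among-taxon identity distributions.
* **Detection filtering** — single-pass crosstalk (tag-jumping) screening of
  sample × taxon read-count matrices (≥0.1% of taxon total, ≥0.1% of sample
  total, ≥40 reads), depositor calling against a predator allow-list, diet
  calling with predator self-detection removal, and wild/domestic
  resolution of *Ovis* and *Capra* items.
* **Genotyping** — multiple-tubes consensus genotypes under fixed evidence
  rules (het ×2, hom ×3, shared allele in exactly two amplified
  replicates), >70% amplification screening, individual matching with
  partial-call semantics, allelic-dropout / false-allele rate estimation,
  and PID / PIDsibs panel-resolution statistics.
* **Diet summaries** — frequency of occurrence (FO), relative frequency of
  occurrence (RFO), items-per-scat, rare-item exclusion (<3 scats), food
  item accumulation curves, and depositor summary tables, with full
  precision internally and a single terminal half-away-from-zero rounding.
* **Synthetic data** — a ground-truthed generator (reference barcodes of
  controlled pairwise divergence, multinomial read counts with
  blocking-primer suppression, between-sample crosstalk at a controlled
  rate, per-base sequencing error, replicate genotypes with nominal ADO/FA
  rates) so every stage is testable offline, plus `run_pipeline()` to
  orchestrate everything with one seed and a provenance manifest.

The statistics at the core are standard: RFO(item) = 100 · occurrences /
all occurrences in a region, FO(item) = 100 · scats containing the item /
diet-positive scats, per-locus PID = Σpᵢ⁴ + Σᵢ<ⱼ(2pᵢpⱼ)², and
PIDsibs = 0.25 + 0.5Σpᵢ² + 0.5(Σpᵢ²)² − 0.25Σpᵢ⁴, multiplied over loci.

## Worked example

The package bundles the printed summary counts of a published range-wide
Asiatic cheetah scat survey (376 scats from four regions of central Iran)
as a worked example. Feeding those counts through the summary machinery:

```r
library(scatdiet)

# depositor identification: counts -> per-region percentages
s <- summarize_depositors(expand_depositor_counts())
head(s[s$region == "total", ], 4)
#>  region        depositor   n      pct pct_rounded
#>   total Acinonyx jubatus 138 36.70213          37
#>   total    Vulpes vulpes  82 21.80851          22
#>   total      Canis lupus  59 15.69149          16
#>   total          Felidae  58 15.42553          15

# diet composition: scat counts -> RFO and FO
survey <- cheetah_survey_diet()
dt <- diet_table_from_counts(survey$items, survey$scats)
head(rfo(dt, "total"), 3)
#>            item  n       rfo rfo_rounded
#>     Ovis vignei 80 54.421769          54
#>  Capra aegagrus 31 21.088435          21
#>  Lepus capensis 16 10.884354          11
head(fo(dt, "total"), 3)
#>            item  n       fo fo_rounded
#>     Ovis vignei 80 66.66667         67
#>  Capra aegagrus 31 25.83333         26
#>  Lepus capensis 16 13.33333         13
items_per_scat(dt, "total")$rounded
#> [1] 1.2
```

So 37% of collected scats were confirmed cheetah; mouflon (*Ovis vignei*)
dominates the diet (RFO 54, found in 67% of diet-positive scats), followed
by ibex and cape hare, at 1.2 food items per scat — the survey's published
headline numbers, reproduced from its printed counts.

A fully synthetic end-to-end run with known truth:

```r
design <- default_study_design(c(Touran = 10, Yazd = 10))
res <- run_pipeline(pipeline_config(seed = 1, design = design))
recovery_report(res)[c("depositor_recovery", "diet_recovery")]
```

A thin command-line wrapper lives at `inst/cli/scatdiet.R`
(`Rscript scatdiet.R run --config config.yaml`).

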