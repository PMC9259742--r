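---
title: "Methods: scat DNA metabarcoding diet analysis with scatdiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scat DNA metabarcoding diet analysis with scatdiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatdiet)
```

# The problem

Diet studies of elusive carnivores rely on scats collected in the field, but
field identification of the depositing species is error-prone, and
morphological prey identification from undigested remains is biased by how
predators consume their prey. Scat DNA metabarcoding addresses both: a
mammal-generic marker identifies the scat depositor, a prey marker (amplified
with a blocking primer that suppresses the predator's own template)
identifies the food items, a hypervariable mitochondrial control-region
(D-loop) marker separates wild from domestic sheep and goats where the prey
marker cannot, and a replicated microsatellite panel assigns scats to
individual animals. `scatdiet` implements the computational half of this
design as a reusable, fully testable pipeline, together with a synthetic-data
generator so that every stage can be validated offline against known truth.

# Pipeline stages and their assumptions

## Read processing

Paired reads are merged by exhaustive ungapped overlap search
(`merge_pairs()`): every overlap length between `min_overlap` (default 10)
and `max_overlap` (default 100) is scored by mismatch density, the lowest
density wins, and ties go to the longer overlap. Overlap disagreements are
resolved towards the higher-quality base; *equal*-quality disagreements
become `N` — a deliberate, documented tie-break, since the information to
choose a base simply is not there. The merged quality is the maximum of the
two qualities. Only "innie" overlaps are considered (the merged fragment is
never shorter than either read); amplicons shorter than one read are outside
the model. Indel-tolerant merging is intentionally not implemented: the
markers are short, fixed-length amplicons and the error model of interest is
substitution-dominated.

Merged reads are screened with the expected-error statistic
`EE = sum(10^(-Q/10))` at `maxee = 1` (inclusive, the usual convention) and
a closed length window per marker. Exact-sequence dereplication across
samples yields zero-radius OTUs; OTUs whose pooled count is 1 are removed as
singletons (pooled, not per-sample — dereplication is performed on the
pooled run). Every input read ends in exactly one of retained / rejected /
dropped-as-singleton, and the pipeline asserts these conservation identities
at run time.

## Taxonomic binning

Alignment hits are consumed as tables (query, subject species, percent
identity, query cover); running the aligner itself is out of scope, though
`align_otus()` produces equivalent tables for the synthetic path. Hits are
pre-filtered to full-length alignments (query cover >= 98, inclusive) and to
species present in the study region (geographic masking).

`bin_otu()` assigns each OTU with an LCA-style unanimity cascade over four
inclusive identity thresholds (species, genus, family, above-family; all
default 99): at each rank, from most to least specific, the hits at or above
that rank's threshold must agree on a single taxon; the first unanimous rank
wins, otherwise the OTU is unassigned. Conflicting equal-identity species
thus escalate to their shared genus rather than being broken arbitrarily.

One property deserves care: raising a threshold does *not* universally make
calls less specific. If two conflicting species sit at 96% and 95% identity,
a species threshold of 95 escalates past species, while 96 prunes the weaker
hit and yields a unanimous — more specific — species call. Monotone
degradation (species, then genus, then family, then above-family, then
unassigned as thresholds rise) holds exactly on hit sets that share a single
lineage, which is the regime in which thresholds are tuned; the test suite
asserts it there and demonstrates the conflict counterexample explicitly.

`select_thresholds()` supports data-driven tuning: given labelled
within-taxon and among-taxon identity distributions, it returns the smallest
integer threshold at which the among-taxon fraction at or above the
threshold does not exceed a tolerance (default 0), flags ranks where the
chosen threshold would also cut into within-taxon identities (inseparable
distributions), and enforces rank monotonicity by raising higher-rank
thresholds — which can only shrink the among-taxon false-merge fraction.

## Detection filtering and calling

Detections (sample x taxon read counts) pass a single-pass, three-predicate
crosstalk screen (`filter_crosstalk()`): an entry survives iff it is at
least `taxon_frac` (default 0.1%) of its taxon's total, at least
`sample_frac` (default 0.1%) of its sample's total, and at least `min_reads`
(default 40; a detection of exactly 40 reads survives). All three predicates
are evaluated against the totals of the *input* matrix. The screens are
deliberately not iterated: re-computing totals after each removal would make
results depend on removal order and silently change them; single-pass joint
screening is order-invariant, and the suite verifies row-order invariance.

The depositor is the allow-listed taxon with the highest surviving read
count on the predator marker (ties broken alphabetically for determinism);
family-rank calls (e.g. Felidae) are legitimate when binning cannot resolve
further, and wolf/dog-type ambiguities are reported at the rank binning
gives, never guessed. Diet items are the surviving prey-marker taxa minus
the depositor's own lineage (residual predator reads that escaped the
blocking primer are self-detections); a configurable mask can extend this.
Ovis and Capra items are re-labelled wild or domestic from the D-loop
detections; both labels surviving in one sample is reported as a flagged
conflict, no detection as unresolved.

## Consensus genotyping and individual ID

Replicated PCRs (default 4 tubes, 21 loci) are condensed per locus under
three evidence rules, in order: an identical heterozygote in at least two
replicates; a homozygote in at least three; a single shared allele when
exactly two replicates amplified (accepted with the second allele missing).
Two different heterozygotes each seen twice are contradictory and yield a
flagged missing call. Heterozygote evidence precedes homozygote evidence
because dropout can fabricate a homozygote but not a heterozygote. A
replicate showing a single peak is represented as an apparent homozygote,
because fragment analysis cannot distinguish the two. Samples are screened
on amplification success over a screening panel and must exceed 70%
(strictly; exactly 70% is rejected).

Genotype matching merges samples that agree at every commonly-called locus
(configurable mismatch tolerance, default 0); partial single-allele calls
match any genotype containing that allele, and pairs sharing fewer than a
minimum number of called loci are never merged. Individuals are the
transitive closure of this relation, labelled deterministically in
sample-id order. Whether matching should tolerate missing loci is not
something the evidence rules dictate; the choice above (compare only
commonly-called loci, require a minimum overlap) is fixed and documented
here.

Panel resolution is quantified with the probability of identity under
Hardy-Weinberg equilibrium,
`PID = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2` per locus, and its sibling
analogue
`PIDsibs = 0.25 + 0.5 s2 + 0.5 s2^2 - 0.25 sum(p_i^4)` with
`s2 = sum(p_i^2)`, multiplied over loci. Allele frequencies are computed
from one genotype per identified individual, never per scat, to avoid
pseudo-replication. Both formulas are verified against brute-force
enumeration of genotype pairs to 1e-12.

### Error-rate estimation and its conditioning caveat

Allelic dropout is scored per allele at consensus-heterozygous loci: each
of the two consensus alleles in each replicate is a trial, an absence is a
dropout, fully failed replicates count as double dropout, and replicates
containing a false (non-consensus) allele are excluded from dropout scoring
because a substitution masquerades as a dropout. The false-allele rate is
the fraction of non-failed replicates at fully-called loci containing an
allele absent from the consensus. Under the generator's model these
estimators converge to the nominal rates.

There is, however, an intrinsic subtlety: when the consensus is formed from
the same four replicates it is then scored against, the estimate is
conditioned on the consensus having been accepted (a heterozygote consensus
requires two clean heterozygote replicates), which biases the dropout
estimate downward by roughly a quarter at a true rate of 0.2. The package's
recovery tests therefore score the estimator against the known truth
genotypes (`consensus_from_truth()`), where it is unbiased; pipeline output
reports the consensus-referenced estimate, which is what a field study can
actually observe, and readers should interpret it as a lower bound.

## Diet statistics

Each food item detected in a scat is a single predatory event, so a
region's occurrence total is the sum of per-item scat counts. Items seen in
fewer than three scats in total (strictly; three survives) or flagged as
low-read are excluded on request; there is no automatic read-count cutoff
because judging field contamination is the analyst's call, not a constant.
RFO is an item's occurrences over all occurrences in a region; FO is the
percentage of diet-positive scats containing the item. All computation is
full precision with a single terminal rounding, half away from zero (this
convention, not banker's rounding, reproduces printed report values such as
13/40 = 32.5% rendered as 33%). Accumulation curves average distinct items
over random permutations of scat order and are exact against enumeration on
small inputs.

The bundled worked example carries the printed summary counts of a
published range-wide Asiatic cheetah scat survey (376 scats over four
regions of central Iran). Two internal inconsistencies of the printed
tables are worth recording. First, the printed occurrence-total (149)
exceeds its own per-region breakdown (72 + 7 + 14 + 54 = 147), which also
equals the sum of the listed item counts plus the low-occurrence items
enumerated in the text; the bundled table uses the self-consistent 147, and
every published percentage reproduces identically under either total.
Second, the text reports 119 scats with identified food items while the
table's per-region denominators sum to 120; the table, being
self-consistent with its own percentages, is used. Both appear in the data
documentation.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is validated.

* **Reference barcodes.** One random ancestor per marker; each clade
  receives exactly `round(L * d / 200)` substitutions at clade-private
  sites, so clades differ at exactly `2k` sites and realized divergence
  lands within one percentage point of the target for sequences of 100 bp
  or more (an exact-count design — Bernoulli mutation would scatter
  realized divergence by several points at these lengths). Unreachable
  targets (too few sites for all clades) raise an error. Wild and domestic
  Ovis (and Capra) share a clade on the prey marker — their barcodes are
  identical, forcing the genus-level escalation and D-loop resolution that
  the real markers require — and are divergent on the D-loop marker.
* **Read counts.** Per sample and marker, reads are multinomial over
  template weights: the depositor alone on the predator marker; diet
  species at weight 1 each plus the depositor at weight
  `1 - blocking_efficiency` on the prey marker (full blocking leaves zero
  depositor reads); Ovis/Capra diet species on the D-loop marker. The
  blocking efficiency of the real cheetah blocking primer is not known
  quantitatively — predator amplification was reduced, not eliminated — so
  it is a free parameter, defaulting to 0.9.
* **Errors and quality.** Per-base substitutions at `error_rate` (default
  0.001, no indels — the simplest model that exercises identity
  thresholds); constant Phred scores per read, with a `low_qual_fraction`
  (default 1%) of reads at Q10 to exercise the expected-error filter, the
  rest at Q30. The real quality landscape of a sequencing run is not
  modelled.
* **Crosstalk.** Each read is re-assigned to a uniformly random other
  sample with probability `crosstalk_rate` (default 0.001). Totals are
  conserved: reads move, never vanish, and the suite checks the realized
  misassignment fraction against its binomial envelope.
* **Genotypes.** Per-locus allele frequencies from a flat Dirichlet,
  genotypes under Hardy-Weinberg equilibrium; per replicate, each allele
  of a heterozygote drops independently at `ado_rate`, then with
  probability `fa_rate` one surviving allele is replaced by a uniform
  false allele from the locus's declared range. At most one substitution
  per replicate-locus, so the replicate-level false-allele estimator
  targets `fa_rate` itself.
* **Determinism.** One root seed; every component draws from a child
  stream derived from a fixed text label (`derive_seed()`), so enlarging a
  design does not perturb the draws of existing samples. A fixed (design,
  seed) pair reproduces the run bit-identically.

What the generator does **not** emulate — chimeras, PCR stochasticity
beyond blocking/crosstalk/ADO/FA, length variation within a marker, index
mis-assignment structure beyond uniform exchange, quality-score profiles —
bounds what passing tests show: the pipeline is validated against this
statistical structure, not against every pathology of real runs.

# Problem sizes and numerical choices

Reads are carried internally as weighted groups (unique read pair x
count), so deeply duplicated amplicon data costs one merge per unique
pair. The headline recovery benchmark runs 40 samples at 1e5 read pairs
per marker with crosstalk 0.001 and blocking 0.9 through the entire
merge/filter/dereplicate/bin/screen/call chain, with the per-base
error model switched off for this benchmark: substitution errors either
leave an OTU above the species threshold (one error in ~110 bp) or drop it
below threshold / into singletons, so they do not move detection-level
recovery, and they are exercised separately in read-level tests at smaller
budgets where each erroneous read is materialised individually. Genotyping
benchmarks use 14 individuals, 100 samples, 21 loci, 4 replicates; the
individual-partition recovery check runs on error-free replicates, where
exact recovery is the contract (at ado = 0.2 the occasional
heterozygote-to-homozygote consensus error makes exact partition recovery
of 100 samples a coin flip, which no matching rule can repair), while
locus-level consensus accuracy and error-rate recovery are checked at
ado = 0.2, fa = 0.02.

Other fixed numerical choices: inclusive comparisons at every documented
boundary (maxee, query cover, identity thresholds, the 40-read floor, the
three-scat floor; the 70% genotyping screen is strict by its own
definition); alphabetical tie-breaks wherever a maximum could tie
(depositor calls, OTU ordering), so output never depends on row order;
degenerate inputs (empty hit lists, empty matrices, empty diets,
monomorphic loci) return well-defined values rather than erroring, except
where the input is a contract violation (species missing from the
taxonomy, negative thresholds, unreachable divergence targets), which
errors immediately with a named reason.

# Limitations

The aligner is consumed, not executed; taxonomic resolution can never
exceed that of the supplied reference tables. Read counts are treated as
detection evidence only — no biomass or prey-abundance correction is
attempted, and no preference indices are computed. Negative controls are
logged, not modelled. Sex assignment is consumed as data (a designated
marker column), not inferred. The worked-example tables allow the summary
statistics of the original survey to be reproduced exactly, but the
underlying per-scat detections are not public; statements about real data
rest on the synthetic validation described above.
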