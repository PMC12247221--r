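---
title: "Benchmarking MS/MS spectral similarity models: methods and design"
author: "SpecSimBench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking MS/MS spectral similarity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpecSimBench)
```

# The problem

Molecular networking and analog search both hinge on one primitive:
estimating, from two MS/MS spectra alone, how structurally similar the two
underlying molecules are. Machine-learning models trained on public
spectral libraries promise to outperform algorithmic scores such as the
modified cosine, but their evaluation is fragile in two specific ways.
First, test molecules that are near-duplicates of training molecules
inflate apparent performance (data leakage at the structure level).
Second, a uniformly random test split under-samples exactly the region
practitioners care about: pairs of structurally similar molecules that
are *far* from the training set. SpecSimBench implements an evaluation
methodology that addresses both: library cleaning and metadata
harmonization, a structure-aware train/validation/test split with a
coverage audit, construction of exhaustive and instrument-matched pair
datasets, biased training-pair sampling, retrieval-oriented metrics, and
a modified cosine baseline — all testable end to end on synthetic data.

Throughout, chemical identity means the planar (2-D) structure,
identified by the first 14-character block of the InChIKey
(`inchikey14`): stereoisomers and salt forms of one skeleton count as one
compound. Ground-truth similarity of two structures is the Tanimoto
similarity $|A \cap B| / |A \cup B|$ of their binary fingerprints.

# Structure standardization

`standardizeStructures()` applies, in order:

1. **Largest covalently bonded fragment** — salt/solvate stripping. Ties
   are broken by heavy-atom count, then by the lexicographically smaller
   canonical SMILES, so the choice is deterministic.
2. **Charge neutralization.** Molecules that cannot be neutralized
   (e.g. quaternary ammonium) keep their charge and are recognizable by
   `formal_charge != 0`.
3. **Stereochemistry removal.**
4. **Tautomer canonicalization** by an InChI round-trip: standard InChI
   normalizes mobile-hydrogen tautomers to one representation, and
   regenerating a structure from that InChI yields one deterministic
   canonical member of the tautomer family (e.g. 2-hydroxypyridine and
   2-pyridone map to identical canonical SMILES). We chose this route
   because it is deterministic, stable under re-application, and relies
   only on the InChI algorithm rather than an energy heuristic; its
   behavior differs from energy-based tautomer scorers for some exotic
   tautomer systems, which we accept and document.

The order (neutralize before tautomer canonicalization) matters in
principle; it is fixed as listed and idempotence of the whole pipeline is
tested (standardizing a canonical SMILES is a no-op).

## Fingerprints

Similarities use deterministic **2048-bit linear-path fingerprints**:
all simple paths of 1–7 bonds on the heavy-atom graph are enumerated,
each path's canonical string (element symbols and bond orders, read in
the lexicographically smaller direction) is hashed, and each distinct
path sets two bit positions. Parameters (length 2048, maximum path
length 7, 2 bits per path) are recorded in the `Fingerprints` object.
Path length and bit density follow common practice for Daylight-style
path fingerprints; the implementation is the package's own because no
2048-bit path fingerprint is otherwise available to it, and its outputs
are validated structurally (identity, symmetry, known set-arithmetic
cases) rather than against any external bit layout.

# Metadata harmonization

MGF is the peak-exchange format (dialect: `TITLE`, `PEPMASS`, `CHARGE`,
plus `ADDUCT`, `COLLISION_ENERGY`, `IONMODE` as `KEY=VALUE`), with all
remaining metadata in a companion CSV keyed by `spectrum_id`; a combined
one-record-per-spectrum JSON is also supported. Three harmonization
rules ship as editable CSV files under `inst/extdata/`:

* **Collision energies** are recovered from free-text compound names and
  instrument fields by an ordered regular-expression rule list
  (`collision_energy_rules.csv`); the first match wins and values are
  reported in eV. Normalized collision energy (NCE, a percentage) is
  deliberately *not* converted — there is no instrument-independent
  mapping to eV — so `"HCD 27% NCE"` parses as missing.
* **Adducts** map to canonical bracket notation via a curated list of
  the common positive-mode adducts with their mass offsets and charges
  (`adducts.csv`); spelling variants normalize to one canonical form and
  unknown adducts become missing rather than guessed.
* **Instrument annotations** propagate to ionization method, mass
  analyzer, dissociation method and manufacturer via case-insensitive
  word-boundary rules (`instrument_rules.csv`), e.g.
  `"CID, ESI, Q-Exactive"` yields (ESI, Orbitrap, CID, Thermo). If two
  rules disagree on a field, all four derived fields are dropped for
  that record (conflicting evidence is worse than none). Explicit
  provenance values always override derived ones.

# Quality filters

`selectForMl()` applies, in a fixed order: source-library exclusion;
missing-structure drop; ion-mode filter (records with unknown ion mode
are dropped — polarity cannot be verified); precursor mass ceiling
(1500 Da); precursor validation; peak preprocessing; significant
fragmentation. The drop report attributes each spectrum to the *first*
rule that rejected it, so `kept + sum(drops) = input` always holds; the
kept set itself does not depend on the order of the independent
per-spectrum rules.

Precursor validation compares the observed precursor m/z against
$(M + \mathrm{offset}_{\mathrm{adduct}})/|z|$ and keeps records within
50 ppm (ppm computed against the theoretical value). Peak preprocessing
rescales intensities to the base peak, then removes peaks with relative
intensity strictly below 0.1% (a peak exactly at the threshold is kept),
then removes peaks outside the inclusive 10–2000 Th window; the boundary
conventions are documented because the verbal rules do not decide them.
"Significant fragmentation" requires strictly more than 4 peaks with
relative intensity strictly above 2%, read literally: exactly four
qualifying peaks fail.

# The structure-aware split

`splitStructures()` operates on the all-pair Tanimoto matrix of the
deduplicated structures, in three phases, all driven by one seed:

1. **Dissimilarity seeding.** Each structure is binned by its maximum
   similarity to any other structure; up to `dataPointsPerBin`
   structures are drawn per bin. The histogram uses the balancing bins
   on [0.4, 1] plus one underflow bin below 0.4, so maximally isolated
   structures are also eligible — the point of the phase is to guarantee
   the test set contains structures the training set cannot explain.
2. **Random-walk neighborhoods.** A graph connects structures with
   similarity strictly above 0.7; roots are drawn among nodes of degree
   at least 4 ("degree greater than three", read literally) and a
   4-step uniform random walk from each root moves the root and all
   visited nodes to the test set. Walks may revisit nodes; the returned
   set is deduplicated.
3. **Erosion balancing.** Test structures are binned into
   `nTtBins` evenly spaced train-test-similarity bins on [0.4, 1]
   (default 13). Starting at the lowest underfilled bin, structures are
   sampled from the next non-empty higher bin, and for each sampled
   structure every training structure with similarity strictly above
   the current bin's upper bound is removed — which forces that
   structure's train-test similarity down into (or below) the target
   bin. If the donor bin cannot supply enough structures, all of it is
   taken and the next bin is consulted on the following iteration. The
   loop stops when all bins are full, when no further progress is
   possible, or when 80% of the original training pool has been eroded.
   The validation set (default 500 structures) is drawn uniformly from
   the surviving training pool at the end.

Train-test similarity of a test structure is the maximum Tanimoto
similarity to any (final) training structure; for a spectrum pair it is
the mean over the two structures. One known bin-geometry tension is kept
visible rather than resolved: the balancing loop defaults to 13 evenly
spaced bins on [0.4, 1], while the audit grid below uses 12 bins of
width 0.05 (the geometry implied by a 120-cell grid with a 30-cell
region of interest); `nTtBins` is configurable, and the split tests run
with 12 bins so bin boundaries fall on multiples of 0.05.

## The coverage audit

`coverageGrid()` bins ordered test pairs by (pairwise similarity × mean
train-test similarity) into a 10 × 12 grid (0.1 × 0.05 cells; bins
left-inclusive, top bins closed). A cell is *covered* at ≥ 200 ordered
pairs (100 unique pairs), and the summary reports overall coverage plus
coverage of the region of interest — pairwise similarity > 0.5 with
train-test similarity in (0.55, 0.85) — the zone of structural analogs
genuinely distant from training. Pairs with mean train-test similarity
below 0.4 lie outside the grid and are tallied separately; they remain
part of the split. At the synthetic-fixture scale the absolute coverage
fraction is small (the 200-pair threshold is calibrated to
library-scale test sets); the package asserts the grid's structural
properties rather than a coverage percentage.

# Pair datasets and biased sampling

`enumeratePairs()` is exhaustive: n spectra give exactly n(n−1) ordered
pairs (self-pairs excluded; pairs of different spectra of the same
structure are allowed and carry target 1.0). The *Filtered* criteria
require identical ionization method, mass analyzer and adduct, collision
energy difference strictly below 5 eV, and precursor mass difference
strictly below 200 Da. Because ~70% of public spectra lack collision
energy, the CE criterion is skipped when either member is missing it,
unless strict mode (`ceRequired`) is on. For the equality criteria a
missing field fails the pair — equality cannot be verified — which is the
conservative reading; only the CE criterion is relaxed on missingness.

`sampleEpochs()` replicates coverage-first training-pair sampling: each
epoch first includes one pair per training structure, then fills the
quota by selecting a non-empty similarity bin uniformly at random and a
pair uniformly within it. Two bin schemes are provided: ten uniform bins
(`uniform10`), and twenty bins with edges $e_i = (i/20)^{0.3}$
(`biased20`). The exponent is applied in this direction because it is
the only reading under which "half of sampled pairs lie above ≈ 0.81"
holds: $e_{10} = 0.5^{0.3} \approx 0.812$, and with equiprobable bins
half the bins sit above that edge. Within-bin selection is without
replacement inside an epoch and independent across epochs. The known
low-end distortion of wide low-similarity bins is accepted as a property
of the scheme, not corrected. Epochs serialize as a directory of keyed
Parquet tables (`epoch_0000.parquet`, ...), one table per epoch, and
test pairs as a single Parquet file.

# Retrieval metrics

Metrics consume a *prediction table* — one row per (query spectrum,
candidate spectrum) with the model score and the ground-truth Tanimoto
similarity — and are pure functions, so multi-seed aggregation is a
separate helper (`aggregateSeeds()`).

* **Binned RMSE** (`binnedRmse()`, `binAveragedRmse()`): RMSE within ten
  ground-truth similarity bins, plus the unweighted mean of per-bin
  RMSEs above a threshold (e.g. 0.6), which weights the structurally
  related region the way downstream applications do.
* **Top Candidate Similarity** (`topCandidateSimilarity()`): mean over
  queries of the maximum ground-truth similarity among the top-k
  predicted candidates. Its **theoretical maximum** is reported in two
  readings, because the verbal definition ("average of the kth highest
  similarities") conflicts with its use as a single attainable bound:
  mode `"max"` (the attainable bound, constant in k; the default
  interpretation) and mode `"kth"` (as quoted). Both are computed; no
  intent is guessed.
* **Top-Rank** (`topRank()`): ground-truth candidates are dense-ranked at
  the structure level — all structures sharing a ground-truth value
  occupy one rank, the next value the following rank — and the metric is
  the minimum predicted rank among the true top-k set, averaged over
  queries. Predicted-side ties are broken deterministically by candidate
  id (the ground-truth-side tie rule is part of the metric definition;
  the predicted-side rule is ours, chosen for reproducibility). Queries
  with no eligible candidate after exclusions are skipped and counted.
* The identical-structure exclusion (`excludeIdentical`) removes
  candidates sharing the query's `inchikey14`, switching the evaluation
  from re-identification to analog search.
* `stratifyByTt()` recomputes any metric inside 0.05-wide train-test
  similarity bins, the generalization-vs-leakage axis of the benchmark.

# Modified cosine baseline

`modifiedCosine()` matches peaks directly or shifted by the precursor
mass difference (tolerance 0.10 Th, inclusive), weights peaks as
$mz^{0} \cdot I^{0.5}$ on base-peak-normalized intensities (the
normalization cancels in the score and is applied for numerical
hygiene), selects a one-to-one assignment greedily by descending weight
product — mirroring the reference implementations, and a documented
point of inter-implementation variation — and normalizes by the two
weight norms. An exact branch-and-bound assignment mode exists for
oracle testing; on the shipped small-spectrum test cases greedy attains
the exact optimum, and the greedy score can never exceed it. The
implementation is cross-checked in the test suite against an independent
implementation of the same parameterization on deterministic overlapping
spectra.

# The synthetic fixture

`generateBenchmarkFixture()` makes the whole pipeline testable without
any download. Its contract is *statistical*, not chemical:

* **Structures**: 15 scaffold cores (benzene through tetrahydropyran)
  each decorated with up to 20 substituents. Members of a family share
  their core, so within-family Tanimoto is high and between-family low
  (mean separation > 0.2 on the default configuration); all generated
  structures are fixed points of `standardizeStructures()`.
* **Spectra**: each structure's fragment peaks derive deterministically
  from its fingerprint bits through a fixed global bit-to-m/z map, so
  shared substructure implies shared peaks and modified cosine
  correlates with Tanimoto by construction (Spearman ρ > 0.3 across
  filtered pairs at the default noise level; raising the noise rate
  degrades ρ monotonically). Poisson noise peaks and lognormal intensity
  jitter sit on top. What this does **not** emulate: real fragmentation
  chemistry, collision-energy-dependent peak patterns, isotope clusters,
  or instrument-specific noise — so passing tests demonstrate the
  correctness of the pipeline's logic, not model performance on real
  libraries.
* **Metadata**: adducts, instrument profiles, and collision energies
  with 70.72% missingness, the rate reported for public test spectra,
  so the CE-missingness branch of the pair filters is exercised at a
  realistic rate.
* **Planted defects** (bad ppm, sparse fragmentation, excluded library,
  over-limit precursor, missing structure, negative mode) are inserted
  into distinct, otherwise clean spectra at known counts, which the
  selection report must recover exactly.

The default fixture (15 × 20 structures, 5 spectra each ≈ 300
structures / 1500 spectra) is the problem size used by the test suite
and keeps the full suite around half a minute; it is generated in code
at test time and cached per session. The split tests use
`dataPointsPerBin = 6`, `numTestRoots = 8` — scaled to give a test set
of ≈ 100 structures at fixture scale, since the library-scale values
are calibrated to tens of thousands of structures.

# Numerical choices

* Bin edges on decimal grids are rounded to 10 decimals so that values
  like 0.7 compare exactly against the edge 0.7 (left-inclusive bins,
  closed top bin everywhere).
* Tanimoto of two all-zero fingerprints is an error, not a value; empty
  training sets define train-test similarity 0.
* All randomness (split phases, epoch sampling, fixture generation)
  flows from explicit integer seeds through one seeding helper that
  restores the caller's RNG state; identical inputs and seed give
  byte-identical serialized outputs.
* The erosion loop is guaranteed to terminate by the erosion cap plus an
  explicit no-progress guard (a bin that cannot be filled is marked
  exhausted rather than retried).

# Command-line interface

`inst/cli/specsim` is a thin Rscript over `specsimCLI()` with
subcommands `simulate`, `harmonize`, `select`, `split`, `pairs`,
`sample-epochs`, `baseline-score`, `evaluate`; one YAML config per run
(unknown keys are an error listing the valid ones), and every run writes
a `manifest.json` with the config hash, input digests, seed, and package
version.

# Known limitations

* Tautomer canonicalization follows InChI's mobile-H model, not an
  energy ranking; the two disagree on some ring-chain and keto-enol
  edge cases.
* The fingerprint is structurally Daylight-like but not bit-compatible
  with any other toolkit; similarity values are internally consistent
  and should not be numerically compared against matrices computed with
  other fingerprints.
* The shipped collision-energy and instrument rule tables are seed
  lists, deliberately user-extensible; real libraries contain spellings
  they do not cover.
* Negative-mode adduct chemistry is not modeled; negative-mode records
  pass through harmonization untouched and are dropped by the default
  positive-mode selection.

# Session info

```{r}
sessionInfo()
```
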