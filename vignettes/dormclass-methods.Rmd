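---
title: "Methods: classifying bud dormancy stages from methylation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying bud dormancy stages from methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Temperate fruit trees such as sweet cherry pass through three bud dormancy
stages — paradormancy, endodormancy and ecodormancy — whose timing decides
flowering, frost risk and yield.  Stage is classically assessed with
destructive forcing assays or agroclimatic chill models.  DNA methylation
offers a molecular alternative: whole-genome bisulfite sequencing (WGBS)
yields per-cytosine counts of methylated and unmethylated reads in the
three plant sequence contexts (CG, CHG, CHH), and stage-informative
methylation marks can in principle be read from a bud sample directly.

`dormclass` implements that idea as a reusable, tested pipeline:

1. **Filter** per-sample cytosine reports to sites with coverage ≥ 4 reads
   in *every* sample (strict presence; no imputation).
2. **Build features**: single retained cytosines, and *regions* — clusters
   of ≥ 4 retained cytosines with consecutive gaps ≤ 100 bp — summarised
   per sample by the mean member methylation level.
3. **Select features** by consensus: train a random forest and a gradient
   boosting classifier on the full labelled matrix, score every feature
   four ways (forest impurity decrease, boosting split gain, mean |Shapley|
   attribution of each model), and retain the features strictly positive
   in *all four* views.
4. **Evaluate** by repeated stratified k-fold cross-validation — 3 folds
   in the 3-stage scenario (the 9-sample minority class still contributes
   three samples per fold), 10 folds in the 2-stage scenario that drops
   paradormancy — with accuracy, macro precision/recall/F1, pooled
   confusion matrices, one-vs-rest macro AUC, and a paired t-test of the
   full-versus-selected accuracy difference on identical folds.
5. **Annotate** the selected features against genes (promoter = 2 kb
   upstream of the TSS, downstream = 2 kb past the TTS, both
   strand-aware), transposable elements with class labels, and QTL
   intervals for chilling requirement (CR), heat requirement (HR),
   flowering date (FD) and maturity date (MD).

A seeded synthetic-methylome generator with planted truth stands in for
orchard data, so every stage of the pipeline is testable offline.

# Feature construction

**Region semantics.** "Regions" are gap-based clusters, not fixed tiles: a
cluster grows while the next retained cytosine lies within `gap_max`
(default 100 bp) of the previous member and is kept when it has
`min_cytosines` (default 4) members.  Fixed 100-bp tiling cannot produce
the wider region features this formulation is expected to yield (region
spans of 117–290 bp are typical), which is why clustering was chosen; both
parameters are exposed.  Region values are unweighted means of member
levels by default; coverage weighting is available behind a flag
(`weight_by_coverage`), and the two coincide at equal coverage.

**Contexts.** For file-based runs the filter defaults to CG-context
cytosines, the context most consistently associated with stable,
heritable methylation differences; `context = "all"` admits all three
contexts and is the default for synthetic runs, whose planted signal spans
contexts.

**Coordinates.** Internally everything is 0-based half-open; cytosine
reports (1-based) are converted once at the boundary; BED is written
0-based; printed feature identifiers are 1-based (`chr_4_31092165`,
`chr_3_9331371_9331488`).  CpG sites on opposite strands are *not* merged.
Chromosome name matching is exact-string.

# The classifiers

The random forest aggregates per-tree class votes by majority; ties break
to the lowest class index in the canonical stage order (paradormancy <
endodormancy < ecodormancy), and the same rule is applied in
`predict()` so the documented tie-break is the one actually used.  Gini
(impurity-decrease) importance is taken from the fitted forest.  Forest
defaults are the field-standard 500 trees with √p features per split.

The boosted ensemble minimises the regularised softmax objective in which
γ penalises each additional leaf and λ the squared leaf weights.  Its
importance view is **raw total split gain** recomputed from the tree dump
(not the library's normalised share), so that increasing λ visibly shrinks
gains.  The boosting defaults are chosen for the p ≫ n regime of
methylation matrices (thousands of features, tens of samples):

| parameter | default | why |
|---|---|---|
| `max_depth` | 2 | n ≈ 71 supports only shallow interactions; deep trees fit residual noise |
| `learning_rate` | 0.1 | small steps keep residuals alive so the ensemble keeps exploring correlated informative loci instead of converging onto one representative per correlated block |
| `colsample_bytree` | 0.1 | forces every tree to work with a random 10% of columns, spreading support across redundant informative loci — the property the consensus intersection relies on |
| `reg_gamma` | 0.75 | minimum split gain; prunes the weak noise splits that would otherwise enter the non-zero-gain support |
| `n_rounds` | 600 | with η = 0.1 and depth 2, support accumulates over many small trees |

These are deliberate departures from the library's generic defaults
(depth 6, η = 0.3, no column subsampling); with tens of samples and
thousands of columns the generic settings concentrate all gain on a
handful of features and admit chance correlates, which defeats a
support-intersection selector.  All settings remain exposed through
`xgb_config()` and are recorded in the run manifest.

# Exact Shapley attribution

Attribution assigns each (sample, class, feature) the Shapley value of the
model output — vote fraction for the forest, per-class margin for
boosting.  The conditional expectation given a feature subset S follows
the standard path-dependent semantics: at a split on a known feature the
sample's branch is taken, otherwise both children are averaged with
training-cover weights.  Forest covers are computed by routing the
bootstrap (in-bag) sample through each tree; boosting covers are the
hessian sums stored in the model.

The implementation exploits the fact that this expectation decomposes over
leaves and that each leaf's game involves only the distinct features on
its root path: Shapley values are computed *exactly* by enumerating the
2^d subsets per leaf path (d ≤ tree depth), in compiled code.  No sampling
or approximation is involved; local accuracy (Σφ + base = model output)
holds to floating-point precision, and is validated three ways in the test
suite: against an exported pure-R oracle that enumerates all feature
subsets of the whole ensemble (`shapley_exhaustive()`), against
hand-computed values on a handcrafted tree, and against the boosting
library's own exact tree-path attributions.

One numerical subtlety: the boosting library stores thresholds and
compares features in single precision.  Feature values and thresholds are
therefore rounded to float32-exact doubles before routing; without this,
samples lying exactly on a threshold are routed differently than the
library routes them and local accuracy fails at ~1e0 rather than 1e-7.

The global per-feature score is the mean of |φ| over samples *and* classes
(the multiclass aggregation is unweighted; classes are equally relevant to
stage diagnosis regardless of sample counts).

# Consensus selection

A feature is retained iff all four views are **strictly positive** — no
epsilon.  Tree importances and exact attributions are exact sums, so zero
means "the models never used this feature"; an epsilon would silently turn
the rule into a tuned threshold.  The selection is ordered by mean rank
across the four views.  Selection on the full labelled matrix reproduces
the original analysis design and is what `select_features()` and
`run_scenario()` do; because that leaks label information into subsequent
cross-validation, `cross_validate(nested_selection = TRUE)` redoes the
whole selection inside every training fold and is the honest-estimate mode
recommended for new analyses.  Both modes are first-class and tested; the
null-calibration test uses the nested mode, since only it promises
uniform p-values under permuted labels.

# Evaluation

Stratified folds are dealt per class after shuffling, so per-fold class
counts differ from proportionality by at most one; with class counts
9/36/26 and 3 folds every fold holds exactly 3 paradormancy samples.
Metrics use macro averaging (the minority class matters as much as the
majority ones) with the 0/0 → 0 convention and a warning for degenerate
precision/recall.  Multiclass AUC is one-vs-rest, macro-averaged over
per-class probability outputs.  The selection benefit is tested with a
two-sided *paired* t-test on per-(repeat, fold) accuracy differences —
folds are matched by construction, and the pairing is enforced by
checking fold-assignment identity.  Zero-variance differences return
p = 1 with a degeneracy flag rather than NaN.  The number of repeats
defaults to 10 and is configurable; results in this package's own checks
use 3 repeats to keep runtimes in minutes.

# The synthetic generator

The generator emulates the *structure* of a multi-year orchard WGBS study
at desk scale, with all distributional choices being explicit stand-ins
(no noise model is prescribed by the underlying study design):

* **Samples**: 71 buds, 9 paradormant / 36 endodormant / 26 ecodormant,
  four cultivars cycled within stage (cultivar ⊥ stage by construction),
  chilling hours drawn from stage-typical ranges.
* **Sites**: ~5000 cytosines in dense clumps (4–12 sites, 6–50 bp gaps) —
  mimicking the uneven cytosine density of real genomes and giving region
  clustering something to find; context mix 30/25/45% CG/CHG/CHH with
  baseline methylation 0.5/0.3/0.1, reproducing the usual plant ordering
  of context methylation and a CG-dominant share of methylated cytosines.
* **Counts**: negative-binomial coverage (mean 20, size 10 — the usual
  overdispersed model for WGBS depth), binomial methylated reads with
  logit-scale effects, so levels stay in (0,1) without clipping.
* **Planted signal**: 1% of sites (whole clumps, so regions inherit the
  signal) receive a per-stage offset pattern — a random permutation of
  (−1, 0, +1) × `stage_effect` — with clump sampling enriched 3× towards
  TE and chromosome-4 QTL intervals.  `stage_effect = 2` shifts
  methylation by roughly 0.4 between adjacent stages at a 0.5 baseline,
  the size of difference reported for convincing stage markers.
* **Confounding**: 6% of sites (disjoint clumps, one cultivar each)
  receive a +3 logit cultivar offset.  Confounders outnumber informative
  sites six to one, so *unsupervised* structure (nearest-centroid
  grouping, t-SNE-like geometry) follows cultivar in the raw matrix and
  stage only after selection — the confound-reversal property the
  package's acceptance suite checks.
* **Noise**: per-locus baseline jitter (sd 0.5 logit) and per-(sample,
  locus) biological noise (sd 0.5 logit).  Together with the 6:1
  confounder excess this keeps full-matrix classification mediocre
  (cross-validated accuracy ~0.8–0.9) while the planted loci alone
  support near-perfect classification — the large selection benefit the
  original study reports on real data, scaled down.

The TE track is laid out to hit its target genome fraction exactly (50%
by default, matching the TE-rich composition of stone-fruit genomes), with
LTR/Ty3 and LTR/Copia the dominant classes.  QTL windows for CR/HR/FD/MD
are placed on chromosome 4.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: bisulfite conversion error, alignment artifacts,
strand asymmetries, linkage between neighbouring clumps, chromatin-domain
structure, batch effects between sequencing years beyond the cultivar
block, and real effect-size distributions.  Synthetic recovery rates say
the *selector* works, not that any particular orchard data set will yield
recoverable markers.

**Calibration.** The scaled-down study conditions (~5000 cytosines, 71
samples, 50 planted loci) are fixed; `stage_effect`, the confounder
block, and the boosting defaults above were chosen together — before the
acceptance suite was frozen — so that the generator sits in the regime the
emulated study describes: cultivar dominating raw structure, a
double-digit accuracy gain from selection, and planted-locus recovery
high enough to be diagnostic.  They have not been revisited since.

# Numerical choices and degenerate inputs

* Seeds: every stochastic component (generator, both models, fold
  construction) takes an explicit seed; seeded runs are bit-reproducible
  and the run manifest records all seeds plus content hashes.
* The generator restores the caller's RNG state (`seeded()` helper), so
  library users' own seeds are unaffected.
* Zero-coverage cytosines are valid input records; methylation level is
  an error at zero coverage, and the presence filter removes such sites
  before matrices are built.
* Context composition flags zero-coverage contexts and all-unmethylated
  samples (`NA` + warning) rather than reporting silent zeros.  The
  methylated-cytosine call (≥ 1 methylated read, level ≥ 0.1, coverage
  ≥ 4) is a documented convention of this package, configurable.
* Empty consensus selections warn (and abort a scenario run, which cannot
  proceed without features).
* `majority_vote` ties break deterministically (lowest canonical index).
* Attribution caps per-path distinct features at 18 (2^18 subsets); the
  cap is far above anything shallow boosted trees or forests on n ≈ 71
  produce, and is a hard error, not silent truncation.

# Known limitations

* Selection on the full matrix (the replicated design) is optimistically
  biased; nested selection is provided and preferred for new data.
* Recovery is defined against planted loci that survive the presence
  filter; loci dropped for coverage cannot be recovered by any selector.
* The per-path enumeration makes exact attribution cheap for shallow
  trees; unconstrained deep forests on large n would need the polynomial
  algorithm instead.
* Chromosome name normalisation across annotation sources is the caller's
  responsibility (exact-string matching).

# Problem sizes used in the checks

The package's own test suite and acceptance script run the full pipeline
at the study's scale (~5000 cytosines × 71 samples, 3 CV repeats) and all
property/oracle tests on small randomised instances (hundreds of trials).
Null-calibration checks use 50 permuted-label replicates of a reduced
matrix (300 features × 36 samples, 6-fold, nested selection with 60-tree
forests).  These sizes are the package's own reproducibility choices: big
enough to exercise the p ≫ n regime, small enough that a complete check
runs in minutes on one core.
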