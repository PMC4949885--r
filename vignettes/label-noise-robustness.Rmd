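---
title: "Label-noise robustness of SNP-based binary genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-noise robustness of SNP-based binary genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpnoise)
```

## The question

Binary phenotypes collected for breeding programmes — disease resistance,
bolting tendency, seedling vigor — inevitably contain a fraction of wrongly
assigned labels. `snpnoise` provides a complete, seeded simulation pipeline
for asking how fast genomic classification degrades as that fraction grows:
a synthetic sugar-beet population generator, genotype quality control, a
controlled label-flipping mechanism, five classifier families under one
fit/score contract, and nested repeated cross-validation that always scores
predictions against the *original* labels while training only ever sees the
noisy ones.

The central design is a *noise ladder*: mislabel proportions
$p \in \{0, 0.01, 0.025, 0.05, 0.075, 0.10, 0.125, 0.15, 0.175, 0.20,
0.25, 0.30, 0.40, 0.50\}$, from a clean baseline to the theoretical maximum
of one half, at which labels carry no information at all.

## The synthetic population

The real panel this generator emulates is not publicly deposited, so the
package ships a generator whose defaults reproduce its published summary
structure exactly:

* 123 plants from 18 inbred lines — 15 high-vigor lines contributing 99
  plants and 3 low-vigor lines contributing 24. Plants are allocated to
  lines as evenly as possible (remainders to the first lines), a neutral
  choice since only class totals are known.
* 192 SNPs assigned round-robin to 9 chromosomes (21–22 per chromosome).
  Physical positions are not modelled; nothing downstream uses them.
* Root elongation (mm/day) drawn from class-specific normals with means
  12.9 (high) and 2.6 (low) and common SD 1.5, *truncated* at the midpoint
  threshold 7.75. The published distribution is clearly bimodal with no
  visible overlap; truncation makes the class label deterministic given the
  line, so the configured 99/24 split holds for every seed. The SD of 1.5
  keeps the two modes ~3.4 SD from the threshold, i.e. essentially
  non-overlapping, while still showing within-class spread.
* Genetic architecture: a line-level allele-frequency-contrast model. By
  default 40 causal SNPs have allele frequency 0.9 in high-vigor lines and
  0.1 in low-vigor lines; every other SNP draws a base frequency from a
  symmetric Beta(2, 2) clipped to [0.15, 0.85] and per-line frequencies
  from Beta(c·f, c·(1−f)) with concentration c = 50, clipped to
  [0.08, 0.92]. Dosages are Binomial(2, p) draws per plant and marker.
  Forty causal markers are used (rather than a handful) so that the
  top-30 "most informative SNP" subset can retain essentially full
  accuracy, mirroring the real panel's behaviour. The clipping ranges keep
  background markers far from the rare-marker regime, so the minor allele
  frequency filter removes exactly the markers constructed for it.
* Missingness: exactly 738 cells are masked (3.12 % of 123 × 192). One
  designated marker — drawn outside the causal and rare sets — receives 21
  missing calls, putting its call-rate at 102/123 ≈ 0.829, below the 85 %
  filter. The rest are placed uniformly with a cap of 15 missing calls per
  marker, so no second marker can fail the call-rate filter by chance, and
  no sample can lose more than half its genotypes.
* Rare markers: 16 markers outside the causal set are overwritten to carry
  at most 6 minor-allele copies in 246 (MAF ≤ 0.0244), planted for the
  MAF ≤ 2.5 % filter.

One master seed drives everything through a deterministic child-seed scheme
(`child_seed()`, a Lehmer-style integer map), so `syn_beet_population()` is
byte-reproducible and stage-wise independent.

What the generator deliberately does *not* emulate: linkage disequilibrium
decay, recombination maps, genotyping-error structure correlated with
genotype, pedigree relationships beyond the line factor, or realistic
effect-size distributions. Consequences are discussed under *Limitations*.

## Genotype quality control

`run_qc()` applies the fixed editing order: call-rate filter (markers with
call-rate ≤ 0.85 removed, inclusive), imputation, MAF filter (MAF ≤ 0.025
removed, inclusive, computed after imputation — the order the editing
narrative implies). On the default fixture this removes 1 + 16 markers and
leaves 175 fully observed SNPs.

The imputer is a documented k-nearest-sample rule (the original panel's
imputation method is not specified in detail): each missing call is filled
with the mean dosage of the k = 5 nearest samples that observe the marker,
where sample distance is the Euclidean distance over mutually observed
markers normalised by their count, and the mean is rounded half away from
zero to a valid dosage. Fallbacks: marker mode when no neighbour observes
the marker, dosage 0 with a warning for a fully missing marker. No sample
filter is applied (per-sample call-rate is only reported).

## Label noise

`flip_labels(y, p, seed)` samples exactly `round(p·n)` distinct indices
(half rounded away from zero: 123 × 0.5 → 62) and inverts them. Exact-count
sampling, not per-label Bernoulli noise, matches a design in which "a
fraction of the observations" is selected; flipping the returned index set
again restores the input exactly.

Noise is injected once per replicate over the full sample; the outer folds
are then split on the noisy labels, training and tuning see only noisy
labels, and validation predictions are scored against the original labels.
An alternative `flip_scope = "training"` flips independently within each
outer-training partition instead; it is exposed but not the default.

The expected minority frequency after flipping is the closed form
$f + p(1 - 2f)$, which the package exposes as
`expected_minority_frequency()` and uses as a Monte-Carlo oracle: at
$f = 24/123$ and $p = 0.5$ the classes are exactly balanced in expectation.

## The five classifiers

All families implement `fit_model()` / `score_model()` with *higher score =
more likely high vigor* (the positive, majority class); AUC is therefore
invariant to any monotone rescaling of scores. Ties at the label threshold
resolve toward the positive class.

* **KNN** (native). Majority vote among the K nearest training samples by
  Euclidean genotype distance, with weights 1 (uniform), 1 − D or 1/D.
  Raw dosage distances exceed 1, which would make 1 − D negative, so
  dosages are scaled to [0, 1] and distances divided by √m; negative
  weights are clamped at zero. At D = 0 the reciprocal weight is treated
  as infinite: exact genotype matches decide the vote by themselves.
  Neighbour ties at equal distance break by training-sample index, making
  scoring fully deterministic. Grid: K ∈ {1, 3, 5, 7} × three weightings.
* **Ridge logistic regression** (native). logit P(y=1|x) = μ + Σ z_j β_j
  with penalty (λ/2)Σβ_j², intercept unpenalised, maximised by Newton
  iteratively-reweighted least squares to gradient max-norm 1e−6 or 100
  iterations. λ > 0 is required when markers outnumber samples (175 > 123),
  where the unpenalised likelihood is unbounded. When p > n the Newton step
  is solved in the n-dimensional row space of the dosage matrix (the
  optimum lies in it), reducing the cost per iteration from O(p³) to
  O(n³); unit tests verify the two routes coincide. The tuning grid is
  λ ∈ {10⁻³, …, 10³} in powers of ten — a symmetric decade grid around 1,
  since only "the penalty is tuned" is specified.
* **Random forest** (via `ranger`). B trees on bootstrap resamples of n,
  Gini splits over m randomly drawn candidate markers per node, grown to
  purity (no depth cap, minimum node size 1). The score is the fraction of
  trees voting positive, taken from per-tree predictions. Grid:
  B ∈ {1, 5, 10, 50, 100} × m ∈ {2, 4, j}, j = int(log₂(#SNP)+1) = 8 for
  175 SNPs. Seeded and single-threaded for determinism.
* **SVM, linear and RBF kernels** (native solver). Soft-margin C-SVC dual
  solved by sequential minimal optimization with second-order working-set
  selection over a precomputed kernel matrix, to KKT tolerance 1e−3;
  decision value f(x) = Σ αᵢyᵢK(x, xᵢ) − ρ. Kernels: ⟨x, x′⟩ and
  exp(−γ‖x − x′‖²) on raw dosages. Grids: C ∈ {2², …, 2⁹};
  γ ∈ {10⁻³, …, 10¹} in powers of ten (the stated range read as decade
  steps). The solver is validated against libsvm (`e1071`) in the test
  suite; decision values agree to the KKT tolerance. During tuning the
  solver warm-starts along the ascending C path within each (fold, γ),
  which is verified to change nothing but the runtime.

Degenerate single-class training sets yield a constant scorer instead of an
error, so unlucky inner folds cannot abort a replicate.

## Cross-validation design

One replicate at noise level p: flip once; split the 123 samples into 5
outer folds, *stratified* on the observed (noisy) labels; per outer fold,
tune by an inner stratified 5-fold CV on the outer-training partition
(fixed inner folds across all grid points), selecting the grid point with
the highest mean inner validation AUC; refit on the full outer-training
partition; score the held-out fold; record TER, FPR, FNR, TPR, TNR and AUC
against the original labels.

Why stratified: with only 24 negatives, plain random 5-fold splits
regularly produce validation folds with a single true class, leaving AUC
undefined; stratification keeps fold sizes {25, 25, 25, 24, 24} and class
proportions within one sample of the global ones. Plain random splitting
remains available (`stratified = FALSE`). Folds whose validation truth is
single-class are still possible at high noise (stratification follows the
noisy labels); their AUC is recorded as missing and reported as such, never
silently dropped.

Why AUC as the tuning objective: the truth is unavailable at tuning time,
so the inner criterion is computed on noisy labels; AUC is
threshold-independent and comparable across families. Ties break toward the
earlier grid row, which is ordered simplest-first (smaller K, B, C, γ;
larger λ; unweighted before weighted votes) for reproducibility.

FPR and FNR use the identity-consistent standard definitions
FPR = FP/(FP+TN), FNR = FN/(TP+FN), so TPR = 1 − FNR and TNR = 1 − FPR hold
exactly; per-fold AUCs are macro-averaged across the 5 folds × replicates.

`run_noise_ladder()` derives the flip and fold seeds from the (noise level,
replicate) pair only, so all families within a cell face the *same* noisy
labels and folds — a paired design that sharpens family contrasts — while
`run_snp_subset_experiment()` reuses the same seeds so its full-panel arm
is record-identical to the main ladder. Marker subsets (top 50 / top 30 by
the squared point-biserial correlation between dosage and label) are ranked
once on clean labels before any noise is injected; ranking under noisy
labels is deliberately out of scope.

## Problem sizes and runtime

The full historical design is 100 repeats × 5 folds = 500 records per
(family, noise level) cell. The package default is 20 repeats (100
records), which keeps a full KNN ladder under two minutes on one core and
estimates cell means to ±SD/10; `replicates = 100` restores the full
design. The test suite and the bundled acceptance script use 20 repeats
(50 at maximal noise, where between-replicate variance peaks), and thin the
linear models' tuning grids to three points spanning their ranges where
only the qualitative decline shape is being checked — the experiment
configuration exposes `grids` for exactly this purpose.

## Limitations, and what passing tests do (not) show

* The synthetic fixture's counts (738 missing cells, 1 low-call-rate
  marker, 16 rare markers, 175 survivors, 99/24 labels) are exact by
  construction, so QC tests validate the *pipeline*, not the realism of
  the missingness mechanism (which is uniform, not genotype-dependent).
* The default architecture is *strongly* linearly separable: 40 causal
  SNPs with a 0.9/0.1 frequency contrast give a between-class margin far
  larger than in most real panels. One visible consequence: penalized
  linear models tuned by inner AUC remain almost noise-immune here — their
  validation AUC stays near 1 through ~25 % label noise, and the
  "local methods degrade slower than global ones" ordering reported for
  the real panel does not emerge at 20 % noise on this fixture. The
  ordering is signal-strength-dependent; reproducing it would require a
  weaker, more diffuse architecture than the one configured. We keep the
  configured defaults rather than tuning them toward any expected
  ordering.
* At p = 0.5 labels carry no information and every family's mean AUC is
  statistically indistinguishable from 0.5 — but per-replicate AUCs are
  extremely variable there (a model may latch onto the line structure and
  score far above or below 0.5 against the truth), so comparisons at
  maximal noise need many replicates.
* No linkage disequilibrium is simulated, so the marker-subset experiment
  shows robustness of *this* ranking procedure to marker count, not how
  tag-SNP redundancy behaves on real genomes.
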