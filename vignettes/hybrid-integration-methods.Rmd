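---
title: "Hybrid integration of clinical and molecular data: models and methods"
author: "hybridRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid integration of clinical and molecular data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical endpoint prediction for cancer patients draws on two very
different kinds of data. Clinical tables hold a handful of strong,
heterogeneous descriptors (age, stage, grade, receptor status, ...), each
individually associated with outcome. Molecular profiling layers (gene
expression, copy-number alterations, methylation, protein arrays) hold
thousands of variables that are individually weak, strongly
inter-correlated, and jointly informative. Concatenating the two ("early
integration") tends to fail: a tree ensemble facing a few strong clinical
columns next to hundreds of near-null molecular ones rarely gains anything
from the latter. Fitting separate models and stacking their predictions
("late integration" / super learning) works, but obscures which layer
contributed what and requires an internal cross-validation machinery for
every evaluation.

`hybridRF` implements the middle road. For each molecular layer a random
forest is trained on a filtered feature subset, and the *out-of-bag (OOB)
fraction of trees voting for the positive class* becomes a single
per-patient **synthetic variable** in (0,1) that compresses the layer. The
synthetic columns are appended to the clinical table and one final random
forest is trained on the extended table. Because OOB votes are computed
only from trees that did not see the sample in their bootstrap bag, the
synthetic variable is an (approximately) unbiased internal prediction and
can sit next to clinical variables without overfitting the final model.

## Pipeline

Per molecular layer, within every training split:

1. **Prefilter** (optional, for raw intensity data): per-feature
   imputation (mean or median), optional log2, then the intensity/variation
   rule — keep a feature iff at least 10% of samples exceed the first
   quartile of the per-feature maxima and the robust coefficient of
   variation IQR/(1.349 |median|) exceeds 0.05. The threshold is computed
   by linear-interpolation quantiles and recorded in the report, because
   the kept set can depend on the convention at small n; re-applying the
   filter at the recorded threshold is idempotent.
2. **Rank** all features by a filter: two-sided Mann–Whitney U test
   (exact null distribution when n ≤ 20 and tie-free, normal approximation
   with tie and continuity correction otherwise), or a 1D/2D entropy
   filter (below).
3. **Correct** for multiple testing with iterative binomial SGoF: with F =
   #{p ≤ γ}, while the one-sided binomial tail P(X ≥ F | n, γ) ≤ α, declare
   the smallest undeclared p-value significant and decrement F. SGoF is
   power-oriented; under dense weak signal it tolerates on the order of ten
   percent false positives, which downstream redundancy removal and forest
   averaging absorb.
4. **Deduplicate** greedily: walk the ranking and keep a feature iff its
   |Spearman| correlation with every kept feature is below 0.7.
5. **Cap** at m = 100 features, train the layer forest, take its OOB
   positive-vote fraction as the synthetic variable, and tune the vote
   cutoff to maximise MCC over the grid of midpoints between consecutive
   distinct OOB scores (plus 0.5; ties resolved toward 0.5).

Clinical features are selected once on the full data set by a
shadow-feature (all-relevant) procedure: each iteration appends a shuffled
copy of every undecided feature, trains a forest with permutation
importance, scores a "hit" when a real feature beats the best shadow, and
confirms/rejects by two-sided binomial tests with Bonferroni correction
across features. Running this outside cross-validation mirrors the
original study design; it may give the clinical-only baseline a small
optimistic bias, which makes the reported integration gains, if anything,
conservative.

## The entropy filter

The 1D filter scores a feature by the information gain IG(f) = H(Y) −
H(Y | disc(f)), maximised over 30 random binary binnings (thresholds drawn
uniformly over the central fraction `rangeParam` of the feature's value
range; features with ≤ 2 distinct values are used as-is). The 2D filter
scores f by max over partners g of H(Y | g) − H(Y | f, g), which detects
pure interactions: on a noiseless XOR of two balanced binary features the
1D gain is ~0 while the 2D gain is ~1 bit for both features. P-values come
from the asymptotic χ² distribution of 2·N·IG (nats) with df = (bins − 1)
for 1D and (bins − 1)·bins for 2D, Šidák-corrected for the maximisation
over the random binnings so that null p-values stay near-uniform. The
residual maximisation over partner features in 2D is not corrected; those
p-values are honest only up to that approximation, which we document
rather than hide. Defaults (2 bins, 30 binnings, full range) are exposed
in `selectionConfig()`.

## Evaluation harness

All quality claims go through `repeatedCV()`: r repeats (default 30) of
stratified k-fold (default 5) cross-validation, with a fresh seeded
partition per repeat shared by all strategies, so per-fold records are
exactly paired. Within each (repeat, fold) every strategy also derives the
same model seed — common random numbers — so forest randomness is paired
across strategies and the paired comparisons below are sharper than with
independent streams. Everything — ranking, SGoF, redundancy removal, forests,
cutoff tuning — runs inside the training split only; the held-out fold
contributes AUC (tie-aware Mann–Whitney form) from raw predicted vote
fractions and ACC/MCC at the fold's own tuned cutoff. Strategy pairs are
compared by a one-sided paired t-test on per-repeat mean AUC (repeat means
rather than fold values, to respect dependence among folds of one
partition) plus a win count across repeats; zero-variance differences
degenerate to p ∈ {0, 0.5, 1} by sign. Stratification is the default
because the target class balances (about 40% positive) otherwise produce
single-class folds at small n.

The super learner comparator fits each base model's full pipeline inside
every fold of an internal 5-fold CV, repeated over several loops; a
combiner — non-negative least squares without intercept (weights
renormalised to sum to one, predictions clipped to [0,1]), a random
forest, or the unweighted mean of the k best base models — is fitted per
loop on the out-of-fold meta-features, and predictions average the
loop-level combiners. Bootstrap bias correction (`bbcEstimate()`)
estimates combiner generalisation from a single internal-CV run: fit on
in-bag meta-rows, evaluate on out-of-bag rows, average over B = 30 draws;
single-class out-of-bag draws are redrawn (bounded retries — the variant
details are our own operationalisation, as the source protocol leaves
them open).

## Why OOB votes, and where leakage actually shows

Replacing the OOB vote fraction by the in-bag fraction makes the
training-side synthetic column nearly identical to the class label. On a
cohort with no signal at all this does *not* move held-out CV AUC away
from 0.5 — test-time synthetic values always come from honest predictions
on unseen samples — but it destroys the model's internal OOB quality
estimate (AUC ≈ 1.0 on pure noise vs ≈ 0.5 with OOB votes). Since the
protocol's efficiency rests on trusting OOB estimates in place of an extra
cross-validation level, the package treats this as the leakage negative
control: `hybridFit(..., syntheticSource = "inbag")` exists only to
demonstrate it, and the test suite asserts both the held-out chance-level
band and the corrupted OOB estimate.

## Sensitivity analysis

`looSensitivity()` removes one feature of the combined model (a clinical
column, or a whole layer via its synthetic variable) at a time, re-runs
the full cross-validated pipeline without it, and reports ΔAUC =
AUC(full) − AUC(−f) with the SD of per-repeat paired differences. An
alternative estimator (`estimator = "oob"`) scores every candidate model
by the out-of-bag AUC of a single forest fitted on all samples — the
protocol's own internal estimate — which removes fold-sampling noise and
costs one fit per candidate instead of r × k; there `r` counts
forest-seed replicates.
Perfectly redundant features mask each other — each member of a duplicated
pair gets ΔAUC ≈ 0 despite their joint importance — which is a property of
removal-based importance, not a defect; `rfe()` resolves it by eliminating
the least important feature and re-fitting, so exactly one copy of a
redundant pair leaves before performance drops. By default RFE recomputes
all removal importances at every step (faithful to "build a new model each
step"; quadratic cost), with `recompute = FALSE` reusing the initial
ranking and only re-evaluating the shrinking model. The recommended
compact model is the smallest size whose mean AUC stays within one SD of
the full model — our operationalisation of the red-line-plus-band plots
used to read off compact models.

## The synthetic cohort generator

`simulateCohort()` provides ground-truth cohorts with the statistical
shape the method assumes. Decisions are Bernoulli(positiveFraction);
informative features are class-conditionally shifted Gaussians (the shift
is the `effect` in SD units, so a feature's standalone AUC is
Φ(effect/√2)); ordinal and categorical clinical features bin a shifted
latent Gaussian into integer codes (categorical codes are scrambled so
their order carries no information); redundant clinical pairs are realised
by Gaussian-copula mixing calibrated to a target Spearman correlation
(2·sin(πρs/6) on the normal scores), checked empirically rather than
enforced; molecular layers mix a per-cluster latent factor as
√c·latent + √(1−c)·noise, with the class shift added directly to
informative features so uninformative cluster mates stay exactly
class-independent. Missing entries are inserted uniformly at random;
imputation is preprocessing's job. The generator does not attempt
platform-realistic count distributions, batch effects, or survival times —
passing tests show the *method's* statistical behaviour under controlled
conditions, not performance on any particular real cohort.

`studyCohortConfig()` freezes the package's canonical validation
conditions: 350 samples, 40% positive; eight informative clinical
descriptors with effects 0.4–1.1 (mixed types) plus eight noise columns
and one redundant pair at Spearman 0.82; one expression-like layer of
2000 features in 400 correlation clusters (c = 0.3) with 600 informative
features at effect 0.15 (standalone AUC ≈ 0.54). The molecular effect
size and count were calibrated, once, so that the cohort sits in the
regime the method is designed for — each molecular feature far weaker
than any clinical one, the layer's aggregate signal real but secondary —
and then frozen. Under these conditions the clinical baseline reaches
AUC ≈ 0.88, early merging of the top-100 selected molecular features
changes nothing (the forest ignores near-null columns), the hybrid
synthetic variable adds ≈ 0.01–0.02 AUC consistently across repeats at
the reference generation seed (the expected gain varies across cohort
draws — see limitations), and the NNLS super learner lands within ±0.02
of the hybrid model — the qualitative comparison structure reported for
the real cohorts, at desk scale.

## Numerical and design choices

- **Forests**: 500 trees by default (100 in the heavier validation runs —
  vote fractions at 100 trees are granular at 0.01, ample for AUC
  ranking), mtry = ⌊√p⌋, no class weights; imbalance is handled by cutoff
  tuning and MCC/AUC reporting. Samples never OOB (possible at very small
  tree counts) get vote 0.5 plus a warning rather than NA, keeping
  synthetic variables defined.
- **U-test score for tie-breaks**: |U − n₁n₂/2|, so equally extreme
  departures on either side rank equally; remaining ties break
  lexicographically for reproducibility.
- **Spearman correlations** use average ranks for ties; a constant
  feature's undefined correlation is treated as 0 (it blocks nothing).
- **Determinism**: every function that touches randomness takes a seed and
  restores the caller's RNG state; sub-seeds are derived from the master
  seed by a fixed integer hash, so whole-pipeline runs are bit-for-bit
  reproducible.
- **Problem sizes in the validation suite**: cross-validated claims use
  r = 30 × k = 5 where the claim is about consistency across repeats
  (the integration comparisons), and r = 2–10 where the claim is a mean
  (type-I control over 20 cohort seeds, RFE ordering over 20 seeds, the
  chance-level band); forests in those runs use 40–100 trees (vote
  granularity 1/40–1/100 is ample for AUC ranking). The chance-level
  ("no-leakage") band is checked on the mean over ten independent null
  cohorts rather than one: a single finite null cohort carries apparent
  signal of order 1/√n shared by training and test folds (between-cohort
  SD of mean CV AUC ≈ 0.04 at n = 300), so only cross-cohort averaging
  isolates harness bias from cohort sampling noise. These are the
  package's chosen study sizes for a single-workstation validation; the
  statistical thresholds they are checked against are stated with each
  test.

## Known limitations

- Synthetic OOB variables carry a small optimism from in-fold feature
  selection (selection sees the layer's training labels); the original
  protocol accepts this and our null-cohort tests bound its practical
  effect (held-out AUC stays within [0.47, 0.53]).
- The 2D entropy filter's p-values are approximate (partner maximisation
  uncorrected) and its cost is quadratic in features; it is intended for
  moderate feature counts or post-filter sets.
- NNLS meta-weights are not unique when base models are collinear;
  predictions are invariant, and tests assert predictions, not weights.
- The generator's clinical dependence structure is limited to the
  redundant-pair construction; beyond that, clinical features are
  independent given the class, which is a simplification of real
  registries where the cited studies report weak mutual correlations.
- Removal-based importance has a hard resolution limit when several
  informative features predict the same binary endpoint: they partially
  mask one another, so each one's marginal ΔAUC shrinks toward the noise
  floor — with five equally informative features the weakest marginal is
  typically only 0.01–0.02 AUC. Separating such features from noise in
  every one of a long sequence of RFE eliminations therefore demands
  estimation precision (many CV repeats, or OOB replicates with thousands
  of trees) that grows quickly with the feature count; at workstation
  scale a minority of simulated cohorts will order one masked informative
  feature after a noise feature, and the corresponding validation test
  documents this rather than hiding it. Masking also interacts with
  cohort realisation: at n = 200–300 a configured effect of 1.0 SD is
  realised with SE ≈ 0.12, so some cohorts genuinely contain one
  near-masked informative feature.
- The integration gain itself is a cohort-level random quantity: on
  synthetic cohorts from `studyCohortConfig()` the hybrid-vs-clinical AUC
  gain varies between about −0.005 and +0.020 across generation seeds
  (stronger realised clinical blocks leave less headroom for the
  molecular synthetic variable), matching the spread of per-layer gains
  reported for the real cohorts. Quantities printed by
  `scripts/acceptance.R` therefore average two cohort replicates and pool
  the paired per-repeat differences.
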