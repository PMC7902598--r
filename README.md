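# hybridRF

Hybrid integration of clinical and molecular data for binary
clinical-endpoint classification (e.g. deceased vs. alive) with random
forests.

## The problem and the method

Clinical tables contain a few strong predictors; omics layers (gene
expression, copy-number alterations, methylation, protein arrays) contain
thousands of individually weak, correlated ones. Simply concatenating
them ("early integration") usually gains nothing — a forest ignores
near-null molecular columns next to strong clinical ones — while stacking
separate models ("late integration" / super learning) is costly and
opaque.

`hybridRF` implements a hybrid strategy. Per molecular layer, on the
training data only:

1. rank features with a filter — Mann–Whitney U test or a 1D/2D entropy
   (information-gain) filter,
2. correct for multiple testing with the sequential goodness-of-fit
   (SGoF) metatest,
3. remove redundancy greedily at |Spearman ρ| ≥ 0.7, cap at the top
   m = 100,
4. train a random forest and take each patient's **out-of-bag fraction of
   votes for the positive class** as a single *synthetic variable* in
   (0,1).

The synthetic columns are appended to the clinical features and one final
forest is trained on the extended table, with its vote cutoff tuned to
maximise the Matthews correlation coefficient (MCC) on the OOB votes.
Because OOB votes come only from trees that never saw the sample, the
synthetic variable behaves like an honest internal prediction — the final
model needs no extra cross-validation level.

The package also provides the comparators (early merge,
super learner with NNLS / forest / best-k combiners and bootstrap bias
correction), a shadow-feature all-relevant selector for clinical
variables, a repeated stratified cross-validation harness with paired
strategy comparisons (ACC / AUC / MCC, one-sided paired t-tests, win
counts), single-feature-removal sensitivity analysis, recursive feature
elimination, and a synthetic multi-modal cohort generator with known
ground truth.

## Worked example

```r
library(hybridRF)

## a synthetic cohort in the regime the method targets: strong clinical
## block, 2000 weak cluster-correlated molecular features (600 informative
## at effect 0.15), 40% positive class
sim    <- simulateCohort(studyCohortConfig(), seed = 31)
bundle <- sim$bundle
bundle
#> OmicsBundle with 350 samples
#>   clinical: 17 features
#>   layer ge : 2000 features
#>   decision: 136 positive / 214 negative

sel <- selectionConfig("utest")   # rank -> SGoF -> redundancy -> top-100
strategies <- list(
  cd     = clinicalStrategy(nTrees = 100, name = "cd"),
  early  = earlyStrategy(selection = sel, nTrees = 100),
  hybrid = hybridStrategy(selection = sel, nTrees = 100))

records <- repeatedCV(bundle, strategies, r = 10, k = 5, seed = 7)
aggregate(auc ~ strategy, records, mean)
#>   strategy       auc
#> 1       cd 0.8739243
#> 2    early 0.8583997
#> 3   hybrid 0.8937305

compareStrategies(records, "hybrid", "cd")
#> hybrid vs cd (auc): mean 0.8937 vs 0.8739, diff +0.0198
#>   paired one-sided t = 4.85, p = 0.000455, wins 10/10
```

Early merging of the selected molecular features leaves the clinical
baseline essentially unchanged (the forest ignores the individually weak
molecular columns; the small difference is not significant at r = 30),
while the hybrid model's synthetic gene-expression variable adds a
consistent AUC gain across cross-validation repeats. A fitted `hybridFit()` model can be inspected
(`syntheticNames()`, `tunedCutoff()`) and interrogated with
`looSensitivity()` / `rfe()` to find a compact model.

A thin command-line wrapper over the same functions lives in
`inst/cli/hybridrf.R` (`simulate`, `preprocess`, `select`, `evaluate`).

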