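---
title: "Methods: explainable bitter/sweet classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable bitter/sweet classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models
and procedures, the parameters that matter, the numerical choices, and
what the synthetic test bed does and does not demonstrate about real
taste data.

## The problem and the pipeline

The sweet/bitter dichotomy is modelled as binary classification of
molecules, represented by SMILES strings, with labels encoded
bitter = 0, sweet = 1. The pipeline has eight stages — curation, 2D
descriptor computation, table cleaning, cross-validated modelling,
statistically corrected model comparison, correlation-aware feature
selection, Shapley-value explanation, and a fingerprint applicability
domain. Each stage is an exported function family and can be used
alone; `README.md` shows the composed flow.

## Curation

SMILES handling is delegated to the OpenBabel backend (via
ChemmineR/ChemmineOB): parsing doubles as a validity check, and
canonicalization guarantees that two spellings of one structure
collapse to one record. Salt and solvent fragments are stripped by
keeping the largest organic fragment of the canonical form; charges
are left as written, since consistent canonicalization (not chemical
normalization) is what deduplication requires. Duplicate standardized
structures keep their first occurrence; structures recorded with both
taste labels are removed entirely — a structure that the
representation cannot distinguish but that carries contradictory
labels can only inject noise. All removals are counted in a report.

## Descriptors

Only 2D descriptors are computed: everything derives from composition
and the heavy-atom bond graph, so values are independent of conformer
generation. Three families are tagged by a source prefix:

* `OB_` — OpenBabel physicochemical properties (MW, logP, TPSA, Mol.
  refractivity, H-bond donor/acceptor counts, ...).
* `COMP_`/`CMR_` — composition counts parsed from the SMILES (per
  element, halogens) and ChemmineR ring and functional-group counts.
* `TOPO_` — graph invariants implemented in the package: Wiener index,
  graph diameter/radius, eccentric connectivity, Zagreb indices,
  Randić connectivity, Balaban J, molecular path counts of order 2–6,
  and the extreme eigenvalues of Burden matrices weighted by atomic
  mass and by electronegativity.

A descriptor that is undefined for a molecule (a single heavy atom has
no Randić index; a backend failure) is stored as `NA`, never as zero.
This missingness is *missing-not-at-random*: it is caused by the
structure itself, which is why the imputation policies below use
constant out-of-distribution values rather than distributional
estimates. Descriptor counts are a property of the backend and are
never asserted anywhere.

## Cleaning

Cleaning applies four rules in a fixed order — duplicate rows, then
columns with missing fraction ≥ 0.95, then near-constant columns
(modal share of non-missing values ≥ 0.99, computed over non-missing
entries), then entrywise-identical columns collapsed to the
lexicographically first name. The order matters (row removal changes
column statistics) and is part of the contract; the `cleaning_report`
counts are exact and tested against planted defects.

## Per-family preprocessing

Every model family carries a `preprocess_policy`:

| family | winsorize | scale | impute |
|---|---|---|---|
| logistic regression, kNN, MLP | 5th–95th pct | min-max | constant 1 |
| random forest | 5th–95th pct | none | constant −99999 |
| gradient boosting | 5th–95th pct | none | native missing |

Percentiles use the linear-interpolation convention (R type 7), stated
explicitly because winsorization bounds are part of the model
artifact. All statistics are fitted on the training split of each CV
fold and applied to both splits; held-out values are clipped at the
*training* percentiles and may scale outside [0, 1] (they are not
re-clipped). A column that degenerates to a constant within one fold
is scaled to 0 for that fold rather than aborting, since globally
constant columns have already been dropped.

## Models and validation

Five families: logistic regression (`stats::glm`), k-nearest
neighbours (`class::knn`, k = 5), random forest (`ranger`, 500 trees),
gradient boosting (`xgboost`, 100 rounds, depth 6, η = 0.1 — the
native-missing-handling gradient machine), and a multi-layer
perceptron with two fully connected hidden layers of 100 ReLU units
trained by Adam on the binary cross-entropy. The MLP is implemented in
the package as plain matrix code; at the row/feature counts of this
problem a BLAS matmul loop is entirely adequate, and it keeps the
2×100-ReLU-Adam architecture an explicit, testable default. All
hyperparameters are pass-through configuration with logged defaults;
there is no search.

Validation is stratified k-fold cross-validation, repeated with a
fresh randomization per repetition (`cv_spec`); repetition *r* seeds
both the fold assignment and every stochastic learner with
`seed + r − 1`. Metrics: AUROC (Mann–Whitney identity, ties counted
half), AUPRC (average-precision step convention), and F1 / precision /
recall at a fixed 0.5 threshold (precision of an empty positive set is
0, with a warning). Fold metrics aggregate as the mean with a
normal-approximation 95 % CI — the CI method is declared because
percentile alternatives give slightly different intervals.

## Model comparison

Fold scores from resampled CV are positively correlated across folds
(training sets overlap), so the naive paired t-test is
anti-conservative. The corrected resampled t-test inflates the
variance:

t = mean(d) / sqrt( (1/n + r/(1−r)) · var(d) ),

with d the per-fold AUROC differences, n = k × repeats, and r the
test fraction, r = 1/k for k-fold CV — so the ratio term is 1/9 for
10-fold. p-values are two-sided from Student's t with n − 1 degrees of
freedom; pairwise comparison over m model pairs multiplies p by m
(Bonferroni). Identical score vectors define t = 0, p = 1. Under a
simulated null the test is conservative (empirical rejection well
below α), which is the known cost of the correction.

## Feature selection

Descriptor tables are massively redundant. The selection algorithm
makes that redundancy explicit:

1. Rank each descriptor by the two-sample Kolmogorov–Smirnov statistic
   D = sup |ECDF_bitter − ECDF_sweet| (missing values dropped;
   p-values from the asymptotic two-sample distribution).
2. Compute Spearman rank correlations between descriptors
   (pairwise-complete over missing values; undefined pairs set to 0
   with a warning), convert to the distance 1 − |ρ|, and build a Ward
   (`ward.D2`) merge tree once.
3. For each cluster count k: cut the tree, keep the highest-D member
   of each cluster (ties: lexicographically first name), train the
   reference learner (gradient boosting by default) on those k
   features under stratified 5-fold CV, and record the AUROC and the
   mean |ρ| over within-cluster pairs (0 when all clusters are
   singletons).

The absolute value in 1 − |ρ| is a deliberate choice: a strongly
*negatively* correlated descriptor pair is exactly as redundant as a
positive one. The signed alternative (1 − ρ) is available via
`sign = "signed"` for users who want anticorrelated descriptors kept
apart. k = 1 reduces to the single globally most separating feature,
and at k = p the sweep equals a CV run on all features.

KS ranking and clustering are computed once on the full table, before
cross-validation — matching the procedure the selection trace is meant
to reproduce. This means the *selection* is not leakage-free even
though all preprocessing inside each CV fold is; the sweep's AUROC
curve should be read as a model-complexity profile, not an unbiased
generalization estimate. `sequential_sweep(leakage_safe = TRUE)`
recomputes ranking, clustering and representatives inside every
training fold for users who need the unbiased estimate; it no longer
yields a single feature set per k, which is why it is not the default.
`choose_k` supports the fixed-k strategy and a knee rule (smallest k
within a tolerance of the best AUROC).

## Shapley explanations

A prediction decomposes as ŷ = y_base + Σ_j φ(x_j), with y_base the
expected model output over a background sample and φ the Shapley
values of the features; φ > 0 pushes toward sweet. The conditional
expectation in the Shapley value definition is implemented as the
*interventional* (marginal) expectation — features in the coalition
are fixed, the rest are drawn from background rows — because the
observational conditional form is not computable without a density
model of descriptor space.

Two routes compute the same quantity. `exact_shapley` enumerates all
2^M subsets (bounded at M = 20) and is the oracle.
`tree_shap_matrix` parses the boosted trees and computes, per
(row, background row) pair, each leaf's reachability as a function of
the coalition; the Shapley weight of a leaf then has a closed
combinatorial form in the counts of path features that must follow the
explained row (a) and the background row (b):
φ gains v·(a−1)!·b!/(a+b)! for an x-side feature and loses
v·a!·(b−1)!/(a+b)! for a background-side feature. The two routes agree
to ~1e−7 on toy ensembles; the package tests assert 1e−4.

Two numerical details matter. First, xgboost compares features to
thresholds in float32; the parser reads the JSON dump (enough digits
to roundtrip float32) and casts inputs to float32, otherwise replayed
split decisions diverge from `predict()`. Second, explanations are
reported on the probability scale (the model's sweet probability):
per-background-row margin attributions are rescaled by the chord slope
of the logistic link between the two margins, which preserves
additivity on the probability scale exactly; the margin scale is
available via `scale = "margin"`.

Global artifacts: importance as the column mean of |φ| (descending,
ties by name), beeswarm summary data with per-value percentiles, and
dependence data with a cut-off point defined as the zero crossing of
an isotonic fit of φ against the feature — reported only when the φ
sign actually changes, since the underlying plots mark such cut-offs
but never define them; an isotonic fit is the weakest assumption that
yields a unique crossing. Local profiles rank features by |φ|,
truncate to the top n and aggregate the remainder, preserving the
additive reconstruction.

The background defaults to the explained table subsampled to ≤ 256
rows under a fixed seed: interventional attributions cost
O(rows × leaves × background), and 256 rows keep the estimator's
Monte-Carlo error well below the attribution magnitudes at these
problem sizes.

## Applicability domain

Predictive reliability is framed as similarity to the training
chemistry. Radius-2 circular fingerprints are computed by the backend
(ECFP4) and folded to exactly 1024 bits. A query's score is the mean
Tanimoto similarity to its 5 most similar training compounds (self
excluded when scoring training members — otherwise every training
score is trivially 1). The threshold is calibrated from a stratified
90:10 split (one fold of a 10-fold assignment): by default the 5th
percentile of the validation score distribution, i.e. the domain is
drawn where 95 % of held-out same-chemistry compounds would fall
inside. The rule and percentile are stored in the model and
configurable, since the underlying procedure is only specified up to
"a threshold derived from the two distributions". Scores equal to the
threshold count as inside; an empty fingerprint (degenerate
structures) is outside, with a warning.

## Synthetic study conditions

The generators define the fixed conditions under which the pipeline's
properties are demonstrated:

* `generate_block_table`: 20 blocks × 8 features, within-block
  correlation 0.9 and between-block 0.05 realized by a per-block
  latent factor plus a weak global factor; 5 informative blocks whose
  lead member shifts by 1.0 SD for sweet rows (others by 0.5 SD, so
  the within-block KS ranking is known); 600 rows, balanced classes.
  With these settings the Gaussian-copula Spearman correlation within
  blocks is ≈ 0.89, which is what the intra-cluster statistic recovers.
* `inject_mnar`: value-dependent missingness (upper tail beyond the
  1 − fraction quantile), the deterministic analogue of descriptors
  that fail for particular structures.
* `toy_tree_model`: ≤ 12-feature boosted regression ensembles whose
  last feature is constant during training, so no tree can split on it
  and its Shapley value must be exactly zero (dummy-axiom hook).
* `toy_compound_set` / `demo_compound_set`: homologous series
  (alkanes, polyols, alkylbenzenes) giving controllable similarity
  gradients and a trivially separable 50-molecule demo dataset
  (polyols labelled sweet).

Problem sizes in the tests (10 sweep seeds at k = 20; 500 simulated
null comparisons; 8 label permutations per model family on 600 rows;
20 toy ensembles for the Shapley oracle) were chosen so each check has
enough statistical power to fail loudly if the implementation is
wrong, while a full suite run stays in the minutes range on one core.
The permutation-null check in particular averages over 8 permutations:
the mean CV AUROC under a *single* fixed permutation carries a few
points of permutation noise, and averaging is the standard
permutation-test design for estimating the null mean.

What passing these tests does **not** show: that real taste chemistry
is separable at the demonstrated AUROCs, that the demo descriptors are
the right ones for real sweeteners, or that the Gaussian block fixture
reproduces the heavy-tailed, discretized marginals of real descriptor
tables. The synthetic results validate the *algorithms* (recovery,
calibration, exactness), not the chemistry.

## Known limitations

* Standardization is a backend contract: no charge neutralization or
  tautomer canonicalization, so two protonation spellings of one
  structure can survive as distinct records.
* The descriptor surface (~60 descriptors) is far smaller than the
  thousands produced by dedicated descriptor generators; the pipeline
  is agnostic to the count, but absolute performance on real data
  depends on descriptor coverage.
* Tree-based Shapley attribution is exact only for the
  gradient-boosting family; other families would need the
  model-agnostic kernel estimator, which is out of scope.
* The corrected t-test's variance inflation makes it conservative:
  genuinely different models with small score gaps may not reach
  significance at n = 100 folds.
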