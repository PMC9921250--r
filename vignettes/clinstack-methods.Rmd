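---
title: "clinstack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clinstack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clinstack` is a schema-agnostic toolkit for binary classification of
clinical tabular data. It bundles four stages that are usually glued together
ad hoc: declarative schema-driven ingestion, an automated preprocessing
pipeline, hybrid voting feature selection, and a two-layer stacking
classifier whose meta-layer reads both the class decision and the decision
probability of every base model. This vignette explains the statistical
choices behind each stage, what the synthetic generators do and do not
emulate, and the places where the design was genuinely open.

## 1. The classification model

Six heterogeneous base classifiers are trained in parallel on the same
preprocessed feature matrix:

* `lr` — logistic regression, `logit p = beta0 + x'beta`, fitted by
  iteratively reweighted least squares with an L2 penalty of strength
  `alpha = 0.1` on the coefficients (intercept unpenalised). This is the
  deterministic full-batch equivalent of a stochastic-average-gradient fit of
  the same objective.
* `svm` — RBF-kernel soft-margin SVM. The dual quadratic program is solved
  exactly with `quadprog` (a small ridge keeps the kernel matrix positive
  definite); decision values are mapped to probabilities by Platt scaling
  (a univariate logistic fit). Because the dense QP scales cubically, the
  training subsample is capped (`max_train`, default 1000 rows; seeded).
* `xgb` — gradient-boosted trees with logistic loss. Each round fits a CART
  tree to the Newton pseudo-residuals `(y - p)/h` with hessian weights
  `h = p(1-p)`, so leaf values are Newton steps `sum(y-p)/sum(h)`; splits
  must clear a minimum gain (`min_split_loss = 0.001`, depth 5).
* `rf` — random forest: 60 bagged CART trees of depth 4 (min split 10, min
  leaf 3, `mtry = floor(sqrt(p))`); each tree votes its leaf majority and
  the forest probability is the fraction of positive votes.
* `dnn` — a multilayer perceptron with 3 ReLU hidden layers trained with
  Adam at learning rate 0.01. The published description ("hidden_layer_sizes
  = 3") is ambiguous between 3 layers and width 3; it is read as 3 hidden
  layers of width 32 (configurable), since a width-3 network cannot plausibly
  outperform the linear model it is compared against.
* `cnn` — a 1-D convolutional network that treats the p tabular features of
  a row as a length-p single-channel sequence: conv(32, k=3) -> conv(32,
  k=3) -> conv(64, k=3), all ReLU with same padding and stride 1 (no
  pooling), then dense(128) and a 2-way softmax; Adam at 0.01. Reading the
  feature vector as a sequence is the only input layout consistent with a
  kernel of width 3 applied to 13 features.

Epochs (200), batch size (32), early stopping (10% validation split,
patience 20) are engineering defaults for the two networks; the sources this
package follows leave them unstated. All models expose
`(class, probability)` with the invariant `class = 1(probability >= 0.5)`.

The tree learners share one weighted least-squares CART engine (Rcpp). On
0/1 responses the squared-error impurity is proportional to the Gini
impurity, so the same split criterion serves classification trees, forest
members and boosting on pseudo-residuals.

## 2. Probability-augmented stacking

The framework's core is the second layer. For M base models the meta-feature
matrix has 2M columns, `(class_1, p_1, ..., class_M, p_M)` — each model
contributes its hard decision *and* its confidence. Only the positive-class
probability enters; the negative one is its complement and would be
perfectly collinear. The meta classifier is logistic regression, with the
same L2 strength (0.1) as the base `lr`; the package deliberately reuses
that published value rather than inventing a second tuning constant.

Two baselines frame the comparison: *classical stacking* (meta-features are
the M class columns only) and *traditional majority voting* (strict count
majority; an even-M tie is broken by the mean positive probability, and an
exact tie of both goes to the positive class — ties must be defined
somewhere, and this choice is recorded rather than implicit).

**Out-of-fold discipline.** How the meta layer's *training* features are
produced is the largest unstated choice in this architecture. In-sample base
predictions leak: a base model that memorises its training rows hands the
meta layer an over-confident, over-accurate view of itself, and the stack
overfits. `fit_stacked()` therefore generates meta-features out-of-fold:
the training rows are split into `oof_folds` stratified folds, each base
model predicts the rows of a fold after being trained on the others, and
the bases are then refit on all rows for deployment. The protocol record
(fold assignment, seed) is kept on the fitted object so the discipline is
auditable. An `in_sample = TRUE` escape hatch exists for protocol
comparison only.

The out-of-fold fold count trades two biases: with few folds the
fold-models see less data than the deployed models, so the meta-features
the second layer is trained on are slightly less confident than the ones it
will see at prediction time; with many folds the cost is computation. The
default is `oof_folds = 5`, standard stacking practice; raising it to 10
was measured during development and did not change combiner accuracy
beyond noise (Section 6).

## 3. Preprocessing pipeline

Stage order is fixed: duplicates -> imputation -> outlier removal ->
rebalancing -> scaling. Rationale for the two orderings that matter:
imputation precedes outlier detection because the isolation forest needs a
complete matrix; outlier removal precedes scaler fitting so that a single
wild value cannot define a column's maximum.

* **Duplicates.** Rows identical in every feature and the label are reduced
  to their first occurrence.
* **Imputation.** Default is KNN (k = 5): a missing cell is filled with the
  mean (continuous) or mode (other types) of the k nearest rows that observe
  that column, under Euclidean distance averaged over the numeric features
  observed in both rows (averaging keeps partial overlaps comparable).
  The alternative, label-distribution imputation (per-class column
  mean/mode), reads the labels and is therefore only valid on training data;
  unseen rows are filled from frozen training column statistics.
* **Outliers.** Isolation forest (100 trees, sub-sample 256, contamination
  0.05 by default — the sources give none), implemented from the standard
  algorithm: anomaly score `2^(-E[h]/c(psi))` from mean path lengths; the
  top contamination fraction of rows is removed. Z-score and a plain
  density-scan DBSCAN are available alternatives. Removal (not
  winsorising) matches the framework's published comparison condition.
* **Rebalancing.** Seeded random oversampling (duplication) or
  undersampling to equal class counts; off by default since the reference
  cohort's 54.5/45.5 split does not need it.
* **Scaling.** Per numeric column: a D'Agostino–Pearson K² test at
  `alpha = 0.05` decides *standardize* (normal) vs *scale by maximum*
  (non-normal); among normal columns, |skewness| > 1 triggers
  `log(1 + x - min(x))` (tolerating zeros and negatives) before
  standardization. R ships no K² test, so the package implements the
  standard D'Agostino (1970) skewness and Anscombe–Glynn (1983) kurtosis
  Z-approximations; it agrees with `scipy.stats.normaltest` to 1e-10 on
  fixtures (scipy's special-casing of exactly-zero skewness, where it
  substitutes y = 1, is a known quirk not reproduced). Columns with fewer
  than 8 observations, where the test is undefined, are treated as
  non-normal. Plans are frozen at fit time and reapplied verbatim.

During cross-validation the entire pipeline is fitted on training partitions
only; held-out rows get the frozen plan (impute from training statistics,
scale with training parameters) and are never dropped or resampled. The
published account is silent on this; fitting scalers or rebalancing on the
full data would leak test information into the reported metrics.

## 4. Hybrid voting feature selection

Six rankers are implemented; the default hybrid set is the five the
framework names (Pearson, ANOVA-F, RFE, lasso, decision tree), with binned
chi-squared available by configuration. Native scores: |r|, the two-class F
statistic, the chi-squared statistic after equal-frequency binning into 5
bins (count unstated in the sources; 5 is the usual default), elimination
order under a re-fit L2 logistic (last eliminated = best), |coefficient| of
an L1 logistic at a penalty chosen by seeded 5-fold `cv.glmnet`, and CART
impurity-decrease importance. Constant features score 0 and rank last; ties
break by schema column position for determinism.

The vote takes each method's top-x list and intersects them. The published
pseudocode stops there, but an intersection can hold fewer than x features
(disjoint tops); the result is completed Borda-style with the lowest
mean-rank features not already included, recorded separately in `fill_in`,
so the output size is always exactly x. Methods are weighted equally; the
alternative (weighting by score magnitude) would mix incomparable scales.

## 5. Synthetic data: what it emulates and what it does not

`synthetic_spec()`/`generate()` draw features independently within schema
bounds — truncated normal for continuous columns (mean at the range
midpoint, sd = range/6), uniform multinomial for ordinal/categorical,
Bernoulli(0.5) for binary — and drive the label through a logistic model on
a chosen subset of standardized informative features. The intercept is
calibrated by bisection so the expected positive fraction hits
`label_balance` (default 0.5446, the reference cohort's split). Data-quality
defects are injected on demand: per-cell missingness (never in the label),
verbatim duplicate rows, outliers displaced at least six robust standard
deviations on one numeric feature, and log-normal skew so the log-transform
rule has a true positive to detect.

What this deliberately does **not** emulate: correlation between features,
non-logistic label mechanisms, missing-not-at-random patterns, or the joint
distribution of any real cohort. A green test on this generator therefore
establishes that the machinery is correct under its stated assumptions, not
that any particular accuracy will be observed on real clinical data.

Two fixed benchmark families support the test suite:

* `planted_signal_benchmark(k, m, n)` — k informative features with effect
  sizes decaying geometrically from 1.5 (ratio 0.8) among m noise features;
  used to test selection recovery, where expected importance order is known.
* `stacking_benchmark(n)` — six standard-normal features with
  `logit p = -1.1 + 0.9 f1 + 1.3 f2 f3 + 1.1 f4 f5` (f6 pure noise), about
  one-third positives — the adverse-outcome prevalence typical of
  heart-failure cohorts. Two properties make this family a meaningful
  combiner comparison. First, the linear learner captures the main effect
  but is blind to the interactions, while the depth-limited tree learners
  capture the interactions coarsely, so base-model errors are only
  partially correlated. Second, under class imbalance the tree ensembles'
  vote fractions rarely cross 0.5: their hard class decisions collapse
  toward the majority class while their decision probabilities still rank
  rows correctly. A class-only meta layer cannot recover that ranking; a
  probability-augmented one can. Conversely, on a balanced
  single-linear-signal family every base model errs on the same hard rows,
  probabilities duplicate classes, and all combiners tie (the redundant
  class/step columns then cost the richer meta-feature set a fraction of a
  point of estimation variance) — that family is kept for feature-selection
  tests, where it is the right tool, not for combiner comparisons, where it
  is vacuous.

## 6. Numerical choices and measured behaviour

* Meta-layer L2 strength 0.1 (Section 2); IRLS convergence tolerance 1e-10,
  100 iterations cap.
* The combiner comparison is asserted on `stacking_benchmark` (n = 1000,
  10-fold CV, 20 seeds, base trio lr/rf/xgb at reduced ensemble sizes for
  runtime): median accuracies order proposed (0.725) >= classical stacking
  (0.722) >= majority voting (0.705). Two development findings are worth
  recording. On *balanced* families with a single linear signal the
  comparison is vacuous: base errors are strongly correlated, probabilities
  duplicate classes, and a controlled simulation shows the redundant
  class/step columns then cost the wider meta-feature set roughly 0.4
  accuracy points of pure estimation variance — the proposed and classical
  stackers tie to within noise. And the out-of-fold fold count (5 vs 10)
  changes nothing beyond noise. The asserted ordering therefore reflects
  the imbalance mechanism described in Section 5, not a universal
  superiority on every data-generating process.
* The isolation-forest score uses the standard `c(n) = 2 H(n-1) - 2(n-1)/n`
  normalisation with a depth cap of `ceiling(log2(psi))`; rows are ranked by
  score and the top `floor(contamination * n)` removed, so `contamination =
  0` removes nothing.
* Undefined evaluation ratios (zero denominators) are reported as `NA` and
  excluded from fold means with a warning, never coerced to 0 — coercion
  would silently bias specificity/sensitivity summaries on degenerate folds.
* Determinism: every stochastic component takes a seed, RNG state is
  restored after each seeded block, and identical config + seed reproduces
  byte-identical pipeline artifacts (asserted in the suite).

## 7. Known limitations

* The SVM solves the full dense dual; beyond a few thousand rows the seeded
  subsample cap (`max_train`) is doing the work, which is an approximation.
* The networks are plain-R implementations sized for tabular data with tens
  of features; they are not a deep-learning framework and make no GPU use.
* Kernel SVM Platt scaling is fitted in-sample (standard practice would
  cross-fit it); the stacking layer's out-of-fold discipline already
  shields the meta model from the resulting optimism.
* `load_dataset` reads delimited text only (RFC-4180 CSV with header); no
  database or EHR connectors.
* Feature selection in `run_pipeline` runs once on the full data before
  cross-validation, mirroring the published pipeline; a leakage-averse user
  can disable selection or select on a held-out split externally.
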