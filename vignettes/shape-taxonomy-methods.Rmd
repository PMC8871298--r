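---
title: "Shape taxonomies for breath-analyzer curve classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape taxonomies for breath-analyzer curve classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathtax)
```

## The problem

A multi-sensor breath analyzer (an "electronic nose") records, for every
exhalation, one response time series per sensor: a gold-nanoparticle or
metal-oxide chemiresistor reacts to the volatile organic compounds in the
breath pulse, rises, plateaus, and slowly recovers. A room-air baseline phase
is recorded immediately before the breath. The classification task is
two-class (cancer vs control) at the measurement level.

The conventional representation reduces each curve to scalar summaries —
minimum, maximum, average, trapezoidal area under the curve, and the mean of
the stable end part. These discard the curve's *shape*: two curves with
identical summaries can rise at different speeds, peak once or twice, or
recover on different trajectories. `breathtax` implements the alternative:
cluster the curves of each sensor hierarchically, cut the dendrogram at every
k from 2 to 10, and use a measurement's cluster membership at each cut as a
nominal feature. The nested family of cuts is the sensor's *shape taxonomy*;
each cluster is represented by its *characteristic curve*, the pointwise mean
of its members.

## Pipeline and parameters

1. **Screening.** Measurements missing any required sensor trace are
   excluded (`screen_cohort()`), with the reason recorded. Exclusion never
   looks at the class label.
2. **Length equalization** (`equalize_lengths()`). Some traces carry a few
   spurious extra points. The common length is the minimum across traces and
   surplus points are trimmed from the *start*: the stabilized tail feeds
   both the normalization reference and the end-mean feature, so the tail is
   the part worth preserving. A symmetric trim is available.
3. **Baseline normalization** (`normalize_to_baseline()`). Each breath curve
   is divided by the mean of the last `b_tail = 10` room-air baseline values
   (the stabilized sensor level), the R/R0 convention for chemiresistors.
   This removes the ambient-air response and the sensor's raw signal units.
   A difference mode (`breath - reference`) is available; the reference
   magnitude must exceed `1e-9` in ratio mode.
4. **Median filter** (`median_filter()`), window 3, replicate padding.
   Window 1 disables it. The window is deliberately small: it suppresses
   single-point glitches without eroding genuine curve morphology.
5. **Outlier detection** (`detect_outliers()`), described below; flagged
   measurements are removed from every sensor panel so panels stay
   row-aligned.

The stage order equalize → normalize → filter is fixed and validated; the
normalization reference must come from the raw baseline, and filtering last
means the filter also smooths any normalization jitter.

## Outlier detection

Observations (the concatenated per-sensor curves of one measurement) are
projected onto the principal components retaining ≥ 95% of the variance
(capped at n − 1 components). Two distances are computed per measurement:
the **score distance** (Mahalanobis distance inside the retained subspace)
and the **orthogonal distance** (Euclidean norm of the residual outside it).
Cutoffs come from scaled chi-squared distributions fitted to the squared
distances by moment matching — mean m and variance v give scale v/(2m) and
2m²/v degrees of freedom — evaluated at quantile 1 − α (default α = 0.01). A
measurement is flagged when either distance exceeds its cutoff.

Two practical safeguards are part of the method's design:

* **Gross-error prescreen.** A gross outlier (for instance a 10× amplitude
  glitch) owns the leading principal component and inflates the moment
  estimates of its own cutoff, masking itself. Rows whose squared distance
  from the column-median vector exceeds 25× the cohort median are therefore
  kept out of the *initial* clean set — but only when such rows are at most
  20% of the cohort. A "far" group larger than that is structure (a distinct
  curve-shape group), not error, and nothing is prescreened. Gross errors
  are rare by nature; this asymmetry is what lets the detector coexist with
  strongly clustered curve panels.
* **Iterative refit with a trim bound.** The component model and cutoffs are
  re-estimated on the currently-clean rows (scoring *all* rows against the
  clean model) until the flag set stabilizes, at most 10 refits, and never
  trimming more than 20% of rows — beyond that the model would be collapsing
  onto a subpopulation rather than cleaning the cohort.

The reported distances and cutoffs always come from the final model, so the
report invariant — flagged ⇔ a distance exceeds its cutoff — holds exactly.
At α = 0.01 the detector's nominal behavior on clean data is about one
false flag per 100 measurements; exactness claims ("only the planted
outliers are flagged") are therefore tested at α = 0.001.

## Distances, linkage, taxonomies

Two curve dissimilarities are supported. The **Euclidean distance** is the
square root of the summed squared pointwise differences. **Dynamic time
warping** (DTW) is the minimum total cost over monotone alignment paths with
steps (1,0), (0,1), (1,1), local cost |a − b|, and no path normalization; an
optional Sakoe–Chiba band bounds |i − j|. This convention is fixed in the
package and verified against an exhaustive-alignment oracle. DTW absorbs
delays and speed differences in the sensor reaction; note it is therefore
*insensitive* to any monotone time re-parameterization of a curve — a
property that matters when designing synthetic data (below).

Agglomeration is written in the package rather than delegated to
`stats::hclust` because taxonomies must be bit-reproducible: ties merge the
pair whose clusters contain the smallest original indices, a rule `hclust`
does not guarantee. **Complete linkage** takes the maximum inter-cluster
dissimilarity. **Ward linkage** applies the Lance–Williams recurrence to
*squared* input dissimilarities; heights are on that squared scale. On
non-Euclidean dissimilarities such as DTW this is the standard heuristic
extension of Ward's minimum-variance idea; the recurrence remains an exact
algebraic identity for the pairwise-sum form of the Ward merge cost, which
is how the test suite cross-checks it against a naive oracle.

`shape_taxonomy()` cuts one dendrogram at every k in 2..10 by applying the
first n − k merges, so successive cuts are nested *by construction*: the
k-partition always equals the (k+1)-partition with exactly two clusters
merged (no reliance on monotone merge heights, which Ward on arbitrary
dissimilarities does not guarantee). Cluster labels are renumbered by each
cluster's smallest member, and characteristic curves are pointwise member
means.

**Membership of unseen curves.** How a held-out measurement obtains its
cluster membership is genuinely open; the package assigns it to the nearest
characteristic curve under the taxonomy's own distance, ties toward the
lower index. This uses only training-derived artifacts and treats the
characteristic curve as the cluster's representative, which is exactly the
role it plays in the fitted model. A `transductive` flag exists to cluster
all data once instead (leakage-prone; off by default, provided because the
alternative reading of the original protocol cannot be excluded).

## Feature selection

Three filters rank columns identically for nominal membership features and
numeric common features: **Information Gain** (H(class) − H(class|feature),
bits), **symmetrical uncertainty** (2·IG normalized by the two entropies,
in [0,1], defined 0 when both entropies vanish), and **ReliefF** (all
instances, `k_neighbors = 10`, Manhattan neighbor search over range-scaled
numeric and 0/1 nominal differences, class-prior-weighted miss updates,
deterministic (distance, index) tie-breaking). Numeric features are
discretized for the entropy filters by 10-bin equal-frequency binning
computed on training data. Selection keeps the `top_m = 26` highest-scoring
columns (one per sensor as a neutral budget; a config knob), ties broken
lexicographically.

ReliefF's neighbor structure means some intuitively appealing invariances
hold only in special cases: duplicating every instance, for example, changes
each instance's k-nearest multiset (it gains a zero-distance duplicate hit),
so weights are duplication-invariant only for features whose differences are
determined by the class. The test suite asserts exactly that case and
otherwise pins the implementation to a brute-force reference.

## Classifiers and evaluation

`train_classifier()` wraps three standard learners: **Naive Bayes**
(categorical likelihoods with Laplace add-1 on nominal columns, per-class
Gaussians on numeric ones), a **linear SVM** (C = 1, one-hot nominal
encoding, probabilities by logistic calibration of the training decision
values — deterministic, unlike internal cross-validated Platt scaling), and
a **Random Forest** (100 trees, √p feature subsampling, seeded). Cancer is
the positive class everywhere.

`evaluate_run()` performs one cycle: a stratified 70/30 train/test split,
then *every* training-derived artifact — taxonomies, discretization bins,
filter scores, the selected feature set, the classifier — is fit on the
training rows only. Metrics are accuracy, sensitivity, specificity (as
percentages, from the confusion matrix) and AUROC by the Mann–Whitney rank
statistic with midrank ties. `run_experiment_matrix()` repeats this
`n_runs` times per configuration with one set of per-run seeds spawned from
a master seed (so splits are paired across configurations) and aggregates
each metric as mean ± t-based 95% confidence interval.
`compare_configurations()` runs a one-way ANOVA across configurations and
pairwise Welch t-tests with Bonferroni multiplication, capped at 1.

The original study protocol ("training and testing cycle 1000 times") does
not state the resampling scheme or whether selection sat inside the loop;
stratified 70/30 resampling with selection inside the loop is the
leakage-safe default here.

## The synthetic generator

`simulate_cohort()` emulates the data model, not the chemistry. Each
sensor's normalized response is a rise–plateau–decay curve (logistic onset,
exponential recovery) around a baseline level of 1; raw traces are
reconstructed by multiplying with the sensor's stabilized room-air level
(default 10 units, 0.5% linear drift across a 60-point baseline phase), so
the ratio normalization recovers the prototype exactly in the noiseless
limit. Defaults mirror a realistic screening cohort: 54 cancer / 85 control
measurements, 26 sensors split 8 GNP / 8 analogue MOX / 10 digital MOX,
T = 120 breath points, per-point Gaussian noise sd 0.05 (5% of baseline),
up to 3 spurious leading points per trace. Class signal is carried by curve
shape: informative sensors (fraction `shape_signal`) draw class-specific
prototype sets, all prototypes pairwise separated by at least
`separation × noise_sd` per time point (default 5). Faults are injected at
configurable rates: missing sensor traces, and gross outliers that scale a
measurement's raw curves by 10. Ground truth (class, prototype index, fault
flags) rides along for recovery tests.

`simulate_shape_only_cohort()` isolates the claim that shape carries signal
beyond scalar summaries. The control prototype is an exact
*time-permutation* of the cancer prototype's values: the single response
pulse's value multiset is split by alternating order statistics into two
halves, each arranged unimodally, yielding a two-pulse curve. Shared
baseline pads (12 points, longer than the 10-point end-mean window) fix both
endpoints. Because the values are identical, minimum, maximum, average,
trapezoidal AUC and end mean of the noisy curves are *identically
distributed* across classes — a permutation is the only construction that
guarantees this for order statistics, which otherwise leak through the time
spent near the extremes. Time reversal, the obvious alternative, fails
differently: DTW is invariant to monotone re-parameterization, and a
reversed unimodal pulse is another unimodal pulse with the same value
profile, so DTW barely sees it. The two-pulse permutation forces any DTW
alignment to pay for the inter-pulse valley; at the default geometry the
prototype DTW distance is ~13× the within-class noise-driven DTW distance.

What the generator does **not** emulate: VOC chemistry, cross-day sensor
drift, humidity and temperature effects, correlated noise across sensors,
and class imbalance in curve quality. Passing tests on this generator
demonstrate that the pipeline recovers planted shape structure and is
leakage-safe — not that any particular clinical accuracy is attainable.

## Numerical choices and degenerate inputs

* Ties everywhere break toward lower indices (merge pairs, membership
  assignment, feature ordering) for bit-reproducibility; the full experiment
  matrix is byte-identical under one master seed.
* Problem sizes in the test suite and acceptance script: the shape-vs-summary
  experiment runs 100 evaluation cycles on a 139 × 26-sensor cohort; outlier
  recovery uses 20 cohorts of 139 × 6 sensors (T = 60); prototype recovery
  uses 139 × 4 sensors at T = 120. These sizes make the whole suite run in a
  few minutes while keeping the cohort geometry of the study design.
* Degenerate inputs fail loudly: all-identical curves warn (all merge
  heights 0), cuts larger than the panel are omitted with a warning,
  zero-variance matrices and single-class label vectors error, an all-zero
  score vector under the `positive` selection policy errors ("no informative
  features"), and a test fold missing a class is redrawn with the next seed
  (at most 10 attempts).
* JSON serialization uses 17 significant digits, the shortest length that
  round-trips every IEEE double.

## Known limitations

* Ward heights are on the squared-dissimilarity scale; compare heights only
  within one taxonomy.
* The DTW implementation is exact dynamic programming, O(T²) per pair; for
  very long series use the Sakoe–Chiba band or the Euclidean distance.
* The outlier detector assumes gross errors are a minority (≤ 20%); a cohort
  that is mostly corrupted will pass screening undetected.
* ReliefF is O(n² p); fine at cohort scale (hundreds of measurements), slow
  for thousands.
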