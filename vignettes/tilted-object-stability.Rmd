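---
title: "Judging the falling direction of tilted objects from geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging the falling direction of tilted objects from geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltfall)
```

## The problem

An object stands on the edge of a table and is tilted outward. Will it
fall off, or topple back onto the table? For a rigid, uniform body the
answer is pure statics: the object tips off once its centroid passes
vertically above the pivot. A psychophysical version of the task shows
observers a tilted object and collects a binary judgment; sweeping the
tilt angle traces out a psychometric curve, and its 50% point — the point
of subjective equality (PSE) — is the observer's subjective critical
angle. Comparing human PSEs, physical ground truth, and the PSEs of
classifier models trained on isolated geometric features asks *which*
geometric information suffices for the judgment, with no forward
simulation of the physics anywhere in the models.

`tiltfall` implements the complete modelling side of this paradigm:
stimulus statics, experiment designs, simulated observers, psychometric
estimation, feature- and image-based classifier models, and the
human-model comparison statistics.

## The statics model and its assumptions

Stimuli are frusta of revolution parameterised by bottom radius $R > 0$,
top radius $r \ge 0$ and height $h > 0$, either uniformly solid or thin
uniform lateral shells ("hollow"). The solid centroid height is
$\bar z = h(R^2+2Rr+3r^2)/(4(R^2+Rr+r^2))$; the shell (lateral surface)
centroid is $\bar z = h(R+2r)/(3(R+r))$, with an optional base-cap term
combined by area weighting. Cylinders and cones recover the familiar
$h/2$, $h/4$ (solid) and $h/3$ (shell) values, and both formulas are
checked in the test suite against independent numeric oracles (volume
integration; a triangulated-mesh surface integral).

Assumptions, stated once:

* **Uniform density.** Solid objects are homogeneous; hollow objects are
  uniform thin shells. Wall thickness is not modelled.
* **Pivot convention.** The base rim is flush with the table edge, so the
  pivot offset equals the bottom radius, and tilt is rigid rotation about
  that rim toward the ground. Ground truth is then
  $\theta_c = \arctan(R/\bar z)$, strictly inside $(0°, 90°)$. This
  convention is the only one we found consistent with all the
  experimental manipulations the designs encode (probability of falling
  off increases with tilt; equal-centroid pairs share $\theta_c$;
  equal-height pairs differ through the centroid alone). Trial angle
  grids may extend beyond $90°$; the label model is well defined there
  (any tilt above $\theta_c$ falls outward). It is a documented modelling
  choice, not an assertion about any particular apparatus.
* **Tie-break.** A tilt exactly at the critical angle is labelled "falls
  back to the table". The balanced case has measure zero on every grid
  used; the convention only pins down the boundary.
* **Hollow objects** default to lateral-surface-only shells (open top and
  bottom). `include_base_cap = TRUE` adds a closed bottom; a
  `centroid_override` column accepts externally tabulated centroids and
  takes precedence everywhere, so either reading of "hollow" — and
  measured values — can be dropped in.
* **Units.** Degrees in every interface; radians only internally.
  Lengths are dimensionless scene units.

An independent brute-force check, `numeric_critical_angle_oracle()`,
discretises the object into mass elements, rotates them about the pivot
in steps, and brackets the rotation at which the mass-weighted mean
horizontal coordinate crosses the pivot, refining by bisection. It shares
no formula with the analytic path and agrees with it to better than
$10^{-4}$ degrees across random solid and hollow objects.

## The synthetic stimulus catalog

The original stimulus dimensions are not redistributed here, so
`stimulus_catalog()` reconstructs an 11-object set by root-finding on the
centroid formulas, satisfying exactly the constraints the four
experimental conditions state:

* **Condition 1A** — four solid frusta of equal volume, jointly varying
  base, height and taper so that centroid heights (and critical angles,
  here 25.6°–79.7°) spread widely.
* **Condition 1B** — three hollow objects sharing base size and
  top/bottom (T/B) ratio, differing only in height: stability is
  controlled by the centroid alone.
* **Condition 2A** — two solids sharing base and centroid height (hence
  critical angle, to machine precision) while differing in height and
  T/B ratio.
* **Condition 2B** — two solids sharing base and height whose critical
  angles differ by exactly 8.5°, the gap obtained by solving for the two
  taper values.

Because the set is a constrained reconstruction, statistics that depend
on the precise original dimensions (trend slopes, model PSE contrasts)
reproduce the *direction and structure* of the published effects, not
their printed magnitudes; the geometry-level quantities the constraints
pin down (the 8.5° gap, the equal-centroid identity) are reproduced
exactly. The bundled angle grids reproduce the published trial counts:
176 trials for condition 1A (11 angles × 4 objects × 2 sides × 2
repetitions) and 156 for each other condition; the repetition counts (2,
2, 3, 3) are the unique integers consistent with those totals.

## Simulated observers

`simulate_responses()` draws independent Bernoulli judgments with

$$p(\theta) = \gamma + (1-\gamma-\lambda)\,
  \mathrm{logistic}\!\left(\frac{\theta - (\theta_c + b)}{s}\right)$$

per object, where $b$ is a signed PSE bias (negative = safe-side bias:
the observer judges objects to fall off at smaller tilts than physics
dictates), $s$ a spread in degrees, and $\gamma, \lambda$ guess/lapse
rates that default to zero (the fitting model has no lapse term; nonzero
values exist to stress-test it). The default cohorts — "adult_like"
($b=-4°$, $s=4°$) and "child_like" ($b=-8°$, $s=8°$) — encode the
qualitative adult-over-child precision ordering and the ubiquitous
safe-side bias; they are tunable configuration, not estimates of any
participant group. `simulate_cohort()` adds between-observer variation by
drawing individual biases around the cohort mean (default SD 2°, a
typical between-subject spread for a threshold task), which is what gives
the group-level t-tests a sampling distribution.

What a green parameter-recovery test establishes: the fitting pipeline
inverts this generative family accurately. What it cannot establish:
anything about sequential effects, lapses of attention, feedback
learning, or reaction times, none of which the generator emulates.

## Psychometric estimation

`fit_psychometric()` fits a maximum-likelihood logistic regression of the
green-response probability on tilt angle, pooling sides and repetitions
(side is not a covariate, and PSE is invariant to relabelling it). The
PSE is $-\hat\beta_0/\hat\beta_1$, and the fitted curve passes through
0.5 there by construction. The link family is isolated behind this one
function so a cumulative-normal variant is a local swap.

Numerical choices:

* **Separation.** Near-deterministic data (common for model-generated
  curves, which are almost step functions) give infinite ML slopes. The
  fit then falls back to a ridge penalty of $10^{-4}$ on both
  coefficients and is flagged `converged = "penalized"`. The estimate is
  always finite and lands inside the empirical transition gap; callers
  who prefer exclusion can filter on the flag.
* **Degenerate data** (a single angle; all responses identical) raise
  typed errors rather than returning a number.
* **Bootstrap.** `bootstrap_pse()` is parametric by default: each
  resample redraws every angle cell's green count from a binomial at the
  fitted probability, refits, and records the PSE; the CI is the
  2.5/97.5 percentile. A `nonparametric` flag resamples trial rows
  instead. More than 50% failed replicates aborts with an
  unstable-bootstrap error; the failure count is reported otherwise.
  Calibration (coverage of the 95% interval between 0.92 and 0.98 over
  hundreds of simulated observers) is asserted in the test suite.

## Classifier models

The geometric "models" ask how well the judgment can be made from one
feature at a time. For a chosen feature (base width $2R$, centroid
height, object height, or T/B ratio $r/R$), `build_training_table()`
assembles one row per (object, angle) over the pooled design grids with
the ground-truth fall label. `loo_predict()` withholds one object,
draws a class-stratified bootstrap of the training rows per iteration
(1000 by default), z-scores predictors by the resampled training
statistics, fits a linear max-margin classifier, and predicts the
held-out object at every angle; aggregated votes become a response curve
that enters `fit_psychometric()` exactly as behavioural data does.

Design decisions worth knowing:

* **The classifier** minimises $\tfrac12\lVert w\rVert^2 + C\sum_i
  \max(0, 1-y_i(w^\top x_i+b))^2$ — an L2-regularised squared-hinge
  linear SVM, solved by BFGS with analytic gradients. No installed R
  package provides a linear SVM, so it is implemented here and
  cross-checked against an external reference implementation on a frozen
  fixture in the tests. $C$ defaults to 1.0 (named but unvalued in the
  source experiments) and is recorded in every run's outputs.
* **Leave-one-object-out** is the cross-validation unit, taken as
  authoritative because testing is defined per held-out object;
  "stratified resampling" is read as a class-stratified bootstrap of
  training rows. Per-object resampling seeds are keyed by sorted object
  id, so catalog row order cannot change any result.
* **Standardisation** is by training-fold statistics (the features span
  very different scales; unstated upstream, recorded here).
* **Extrapolation limit.** A held-out object whose feature value lies
  outside the training range gets a boundary extrapolated from the
  margin geometry; the most extreme object of a catalog is therefore
  estimated worst. This is visible in the worked example and is a
  property of the paradigm, not a bug.
* **Blind models fail in the opposite direction.** When a feature is
  constant across objects (base size in the shared-base conditions), the
  held-out boundary follows the training objects' label mix, which moves
  *against* the physics: the blind model's PSEs anti-correlate with the
  true critical angles. The test suite asserts this failing direction,
  matching the reported behaviour of the base model, rather than a flat
  null profile.

`embedding_pipeline()` generalises the feature models to images: each
(object, angle) scene is rendered by `scene_raster()` — a deterministic
2D orthographic silhouette plus table edge, a stand-in for the original
rendered scene set, feeding the embedding path rather than matching any
image pixelwise — embedded by a user extractor (the bundled
`pixel_embedding()` is an 8×8 block-mean), reduced by PCA to the
components explaining 90% of variance, and classified by the same
leave-one-object-out chain. The tilt angle is not appended; the image
carries it. PCA is fitted globally by default ("retained as final
outputs" reads as a single global reduction); `pca_scope = "train"`
refits it inside each fold for the stricter reading. A
`variance_threshold = NULL` escape hatch skips the PCA, which also makes
the pipeline exactly reducible to a feature model for testing.

## Comparison statistics

* `pse_truth_difference()`: per-responder mean (PSE − ground truth),
  tested against zero; negative means the safe-side bias. Zero-variance
  inputs return the exact null identity (all differences zero) or an
  `exact_shift` flag (identical nonzero shift) instead of an infinite t.
* `linear_trend()`: regression of PSE on the orthonormal linear
  polynomial contrast of object rank, objects ordered by decreasing
  ground-truth critical angle. Because printed slope magnitudes depend on
  the (unstated) contrast coding upstream, slopes are compared by sign
  and ordering only.
* `human_model_regression()`: human per-(object, angle) proportions on
  model proportions, with per-predictor Bayes factors by the BIC
  approximation $\mathrm{BF}_{10} = \exp((\mathrm{BIC}_{reduced} -
  \mathrm{BIC}_{full})/2)$. This deliberately does not reproduce
  prior-based Bayes factors from dedicated packages; the approximation is
  documented divergence. Exactly collinear predictors are flagged and
  fall back to pseudoinverse coefficients.
* `variance_partitioning()`: commonality analysis for 2–3 predictors
  from all-subset $R^2$ values; components always sum to the full $R^2$
  (asserted to $10^{-10}$), and negative shared components (suppression)
  are reported with a flag, never clipped. Percentages of explainable
  variance normalise by the full $R^2$.
* `unique_variance_permutation()`: the difference in unique variance
  between two predictors, with a null built by swapping the pair
  $(x_{1i}, x_{2i})$ within each observation with probability ½. The
  scheme is not specified upstream; rowwise pair swapping is chosen
  because it enforces precisely the exchangeability the null requires,
  and it is recorded in the output. Two-sided p with the add-one
  correction; type-I error calibration is asserted in the tests.
* `weighted_pca_correlation()`: embedding principal components retained
  to 90% variance; per bootstrap resample of scenes, each component's
  scores are correlated with each geometric feature, absolute values
  taken (component signs are arbitrary — the statistic is invariant to
  flipping any embedding dimension), and averaged weighted by
  explained-variance share.

## Reproducibility

`run_pipeline()` executes simulate → fit → models → stats, writes every
intermediate table as CSV, and emits a JSON manifest with the derived
stage seeds and MD5 hashes of all outputs; re-running the same
configuration reproduces every file bit-identically. No function reads
global random state: every stochastic operation takes an explicit seed.

## Known limitations

* The catalog is a constrained synthetic reconstruction; analyses whose
  values depend on the exact original stimulus dimensions reproduce
  structure, not printed magnitudes.
* The rasteriser is a silhouette model: no texture, lighting or
  perspective, so image-based results here characterise the pipeline,
  not any pretrained network. A real network extractor can be plugged
  into `embedding_pipeline()` unchanged.
* Mixed-factor ANOVAs, prior-based Bayes factors, and reaction-time
  analyses are out of scope.
* The psychometric model estimates no guess/lapse asymptotes; simulated
  observers with large $\gamma, \lambda$ exist to probe robustness, not
  to be recovered.
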