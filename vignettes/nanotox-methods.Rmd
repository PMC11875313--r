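---
title: "Methods: harmonized nanotoxicity classification with a PBPK exposure bridge"
author: "nanotox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized nanotoxicity classification with a PBPK exposure bridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotox)
```

## The problem

In vitro cytotoxicity screens of inorganic nanoparticles report percent cell
viability under wildly heterogeneous conditions: particle sizes from a few
nanometres to a micron, administered concentrations spanning ten decades,
exposures from minutes to weeks, and free-text descriptions of composition,
coating, shape and surface charge. `nanotox` turns such records into a
standardized design matrix, trains tree-ensemble classifiers for the binary
safe/cytotoxic endpoint under nested cross-validation, explains the fitted
models with exact Shapley attributions and partial dependence curves, and
extends the classifier to organ-specific in vivo toxicity by replacing the
administered-concentration feature with a time-averaged organ exposure
derived from a minimal physiologically-based pharmacokinetic (PBPK) model.

## Harmonization rules

Records are curated with fixed, auditable rules:

* **Units.** Size in nm, exposure time in h, concentration in ug/mL (the
  CSV headers carry the units).
* **Toxicity label.** Following the ISO 10993-5 convention, viability
  >= 70% of control is *safe* (0), below is *cytotoxic* (1). The rule is
  re-applied to every record; no label enters the pipeline another way.
* **Zeta potential.** Measured values collapse to a four-level class:
  positive (> 10 mV), negative (< -10 mV), neutral ([-10, 10] mV,
  boundaries inclusive), or *not determined* when missing. Where both a
  measurement and a pre-supplied class are present the measurement wins.
* **Categorical imputation.** Missing coating becomes `Unmodified`,
  missing shape `Sphere` — the dominant levels in published corpora.
* **Outliers.** Each continuous feature is screened on the log10 scale
  with the 1.5 x IQR rule using linear-interpolation (type 7) quartiles.
  Flags are advisory: the default excludes flagged records with a logged
  record id, and a curator allowlist (`keep_ids`) retains records that
  survive manual inspection. Zero or negative sizes, concentrations or
  times are rejected before the log transform, which is undefined there.
* **Encoding.** Continuous features are log10-transformed (they are
  log-uniform-ish over decades; the dose-response analysis below also
  works in log10 units). Categorical features are one-hot encoded with
  the *least frequent* level dropped per feature to avoid the dummy
  variable trap; ties break toward the lexicographically smallest level
  so the schema is reproducible. A frozen schema applied to new data
  encodes unseen levels as all-zero blocks with a warning, which is the
  only sensible treatment at prediction time.

The schema records, for every encoded column, the feature and level it came
from, so encoding is invertible and attributions can be grouped exactly.

## Evaluation arithmetic

All confusion-derived scalars use the toxic class as positive and the
decision rule *score >= threshold*. Precision with no positive predictions
and an MCC with a zero factor under the root both return 0, so degenerate
classifiers score conservatively instead of erroring. PR-AUC is computed as
average precision (the step-wise sum of precision times recall increments)
rather than a trapezoid, avoiding the optimistic linear interpolation
between PR points; the PR no-skill baseline equals class prevalence, and a
constant classifier attains exactly that. ROC-AUC is the concordance
probability with ties counted one half, computed from midranks. The
operating threshold maximizes F1 over all distinct scores (plus an
all-negative sentinel), breaking ties toward the larger threshold.

## Training protocol

Model evaluation uses 10-fold nested cross-validation: the outer loop
estimates generalization, the inner loop selects hyperparameters by mean
inner-fold PR-AUC. The inner fold count defaults to 5 — the cost/variance
compromise we use everywhere a second-level split is needed (out-of-fold
stacking uses the same value). All folds are stratified by label; every fit
inside one inner search shares the same seed so that grid points are
compared on identical randomness and duplicate points score identically
(ties then break to the earlier grid point). Per-fold winning parameters
are consolidated into a refined grid (the deduplicated union per
hyperparameter, never larger than the original grid), searched once more on
the full training partition, and the winner is refit on all training rows.
The operating threshold is tuned on the pooled held-out-fold scores of the
winning point, so it never sees in-fold predictions. The package-wide
default seed is 3.

Boosting learners monitor log-loss on a stratified 10% hold-out and stop
after 50 rounds without improvement, up to 5000 rounds; the returned model
predicts with the best round. Three boosting configurations are provided
(depth-wise histogram, leaf-wise histogram, exact greedy splits) alongside
a random forest and extremely randomized trees, all behind one
`classifier_spec` contract (fit + probability scorer), so any conforming
learner is pluggable.

Default hyperparameter grids are deliberately small config data (depth
{3, 6}, learning rate {0.1, 0.3}; forest `mtry` fraction {0.33, 0.6} and
minimum node size {1, 5}), with tree counts governed by early stopping for
boosters and the conventional 100 trees for forests.

## Stacking

The ensemble is a logistic meta-learner over the base models' probability
outputs. Meta-training rows are strictly out-of-fold: each base is refit
`k_meta = 5` times and a sample's meta-feature always comes from the refit
that never saw it. The meta fit uses ridge-penalized IRLS (penalty 1e-3,
intercept unpenalized) so collinear or constant base outputs leave the fit
defined; with a single base the stack is a monotone transform of that base
and preserves its ROC area exactly, which the tests assert. Final base
models are refit on all training rows after meta-training.

## Attribution

Attributions are Shapley values of the model's *probability* output under
interventional (background-replacement) expectations, so local accuracy
holds on the probability scale: base value plus the attribution sum equals
the predicted probability for every sample.

Two exact engines are provided. For probability-averaging forests (random
forest, extremely randomized trees, and any `nanotox_forest`), the
polynomial tree-path algorithm is used: for each leaf and each
(sample, background) pair the path constraints classify each path feature
as *must be present* or *must be absent*, and the Shapley weight of the
leaf has the closed form $(k-1)!\,m!/(k+m)!$ for present-features and
$-k!\,(m-1)!/(k+m)!$ for absent-features, with $k$ and $m$ the two group
sizes. For every other model — gradient boosters are margin-additive, so
per-tree probability attributions do not exist — exact subset enumeration
runs at the original-feature level, where the group count (about ten) keeps
$2^M$ small. Both engines agree with the literal subset-sum definition of
the Shapley value to 1e-9 on small models, which the test suite checks
against an independently coded brute force.

One-hot columns are grouped by *signed sum* per feature — the only grouping
that conserves each sample's total attribution exactly — and global
importance is the mean absolute grouped value, ranked descending with
alphabetical tie-break. Cross-model rank agreement is summarized by
pairwise Spearman correlations. Categorical features are summarized per
level by the median grouped attribution (SHAP distributions are typically
skewed), with full distributions exported for box plots.

## Dose-response curves

Partial dependence overrides one continuous feature to a grid value in
every row and averages the predicted probability. Concentration follows a
sigmoidal trend and is fitted with a four-parameter logistic in log10
concentration; exposure time can be fitted in linear time via the
`log10_x` flag (both parameterizations are selectable). A flat curve makes
the 4PL unidentifiable, so the fit degenerates gracefully to a zero-slope
solution whose slope interval covers zero. Size follows a power-law decay,
linear against log10 size, fitted by ordinary least squares. 95% intervals
come from the fit covariance (t quantiles).

Feature reduction retrains the model on nested prefixes of the importance
ranking and records PR-AUC, ROC-AUC, recall and precision from pooled
out-of-fold scores at each size. The plateau is the smallest prefix after
which the next `patience = 2` additions each gain at most
`epsilon = 0.005` PR-AUC; both knobs are exposed because no canonical rule
exists. With `epsilon = 0` only exactly-zero (or negative) gains count as
non-improving.

## The PBPK model

The minimal model has six compartments — plasma, liver, spleen, lungs,
kidneys, and a lumped *others* that closes the flow balance — with
perfusion-limited exchange and first-order excretion:

$$V_i \frac{dC_i}{dt} = Q_i\left(C_p - \frac{C_i}{P_i}\right)
  - \{i=\mathrm{liver}\}\,k_\mathrm{bile} V_i C_i
  - \{i=\mathrm{kidneys}\}\,k_\mathrm{urine} V_i C_i$$

$$V_p \frac{dC_p}{dt} = \sum_i Q_i\left(\frac{C_i}{P_i} - C_p\right)
  + k_a A_\mathrm{depot}(t)$$

IV boluses add to plasma; SC/IP/PO doses pass through a single first-order
depot with bioavailability F (no first-pass hepatic routing — route detail
is deliberately minimal because IV dominates in vivo nanoparticle studies).
The lungs are flow-limited like every other organ; no venous/arterial
split. Kinetics are linear throughout (no saturable uptake), so doubling
the dose doubles every concentration, and mass balance
(body + excreted = F x dose) is verified to 0.1% on every simulated
trajectory in the test suite. The right-hand side lives behind a single
function so an alternative structure can be dropped in.

Shipped mouse physiology (25 g animal, editable): plasma 1 mL; organ
volumes liver 1.3, spleen 0.1, lungs 0.15, kidneys 0.34, others 20 mL;
organ plasma flows liver 90, spleen 5, lungs 12, kidneys 80, others
283 mL/h (cardiac plasma flow 470 mL/h). These are standard literature
values; the `others` flow closes the cardiac balance.

The public simulator integrates with `lsoda` at tolerance 1e-10. Because
the system is linear and time-invariant, calibration evaluates residuals
through an exact eigendecomposition solution propagated piecewise across
dose events — roughly 40x faster than repeated ODE solves and agreeing
with them to solver tolerance (a dedicated test compares the two paths).

**Calibration** minimizes squared residuals between simulated and observed
organ concentrations with Levenberg-Marquardt in log10-parameter space
(partition coefficients and rates are positive and span decades), box
bounds (P in [1e-3, 1e3], rates in [1e-3, 10]), and seeded multi-start
(default 10; the first start is the bound midpoint or a user init).
Residuals are unweighted concentrations by default; the `log_residuals`
flag switches to log10 residuals, which is the statistically appropriate
weighting when measurement noise is multiplicative and is what the
recovery tests use on lognormal-noise data. A study is accepted only when
the overall Pearson R between fitted and observed concentrations is
strictly above 0.9.

**Exposure.** The bridge metric is the time-averaged concentration
$\hat C_i = \mathrm{AUC}_i(0\!-\!t_\mathrm{tox})/t_\mathrm{tox}$, a
composite trapezoid on a 512-interval refined grid (second-order
convergence on smooth profiles; an IV bolus has a fast distribution layer
near t = 0, which is why the convergence-order test reads the order off a
mono-exponential reduction). For in vivo records, log10 of the target
organ's exposure replaces the administered-concentration feature;
everything else is harmonized identically and the training machinery is
reused unchanged. Records pointing at rejected fits are excluded with a
logged reason.

A known identifiability limit, visible in the recovery tests: with organ
concentrations (and no plasma or excreta) observed, a weak elimination
route is poorly resolved — under the reference scenario (hepatic-dominated
clearance, the canonical nanoparticle disposition) `k_urine` carries much
larger relative error than the partition coefficients. The medians
reported by the acceptance checks pool all parameters.

## The synthetic generator

The generator makes every stage testable without any download. Continuous
descriptors are log-uniform over the published ranges (size 1.5-1000 nm,
concentration 5e-4 to 3.2e6 ug/mL, exposure 0.083-336 h) — the true
marginal shapes are unpublished, so the flattest assumption on the log
scale is used and is config-overridable. Categorical shares follow the
published proportions (e.g. 41.1% SiO2, 74.57% unmodified coatings, 89.62%
spheres, 43.15% negative zeta), with each remainder split over plausible
minor levels.

Labels are drawn from a planted logistic model on centered log10 features
plus categorical offsets. Default coefficients are chosen for *sign*
consistency with the known toxicology — concentration +0.9 and time +0.3
per decade, size -0.45 per decade, cationic particles +0.5, heavy-metal
compositions (Cd, Ag, ZnO, CuO) positive offsets, Ce/Fe compositions and
PEG coating negative — not to reproduce any fitted magnitudes, which are
unpublished. The intercept is calibrated by bisection so the expected
toxic fraction matches the configured prevalence (37.3% in vitro, 16.2%
in vivo). A viability value consistent with each label is synthesized so
the curation rules reproduce the labels exactly. Every dataset carries its
Bayes-achievable PR-AUC (scoring samples by their true generating
probabilities), the ceiling against which trained models are judged.

What the generator does *not* emulate: the joint dependence structure of
real corpora (composition-coating-size correlations), assay-specific noise,
inter-laboratory batch effects, or label errors beyond an optional flip
probability. Passing the end-to-end checks therefore demonstrates that the
pipeline recovers planted structure faithfully at realistic marginals and
class balance — not that any particular real-data accuracy is guaranteed.

The in vivo panel generator draws one formulation per study (sizes
1.2-310 nm, gold/iron-oxide/silver-dominated compositions, IV dosing
100-1000 ug) with study-specific true PBPK parameters (partition
coefficients log-uniform over 0.1-50, excretion rates over 0.01-0.5 per h)
and noisy sparse biodistribution panels; records are study x organ x
assessment-time combinations, about 400 at the default 33 studies. The
reference recovery scenario fixes liver/spleen-dominated uptake (P =
20/8/2/1.5/0.4, k_bile 0.05, k_urine 0.1 per h) with an IV dose of 200 ug
sampled at 8 log-spaced points over 0.25-48 h.

## Numerical choices and degenerate inputs

* ODE tolerances 1e-10 (simulation); eigendecomposition path exact, with
  automatic fallback to the solver if the system matrix is defective.
* Shapley weights via log-gamma to avoid factorial overflow; subset
  enumeration refuses more than 15 groups.
* Quartiles: type 7; zero-IQR vectors produce no outlier flags.
* Single-node (constant) trees attribute nothing and set the base value.
* All-identical scores: ROC-AUC 0.5 by the tie rule, threshold tuning
  returns the single candidate.
* Stratified splits and folds rotate remainders across classes so overall
  fold sizes differ by at most one.
* Test-suite problem sizes are chosen to exercise the full protocol at
  desk scale: n = 5000 for the end-to-end in vitro recovery (10 x 5
  nested CV), 20 replicates for noisy PBPK recovery, 33 synthetic studies
  (~400 records) for the in vivo bridge.

## Limitations

* The five published base-learner families map onto the three xgboost
  boosting configurations plus two ranger forests available here; the
  `classifier_spec` contract accepts any further learner.
* Probability-space tree-path attributions require probability-averaging
  ensembles; margin-additive boosters use exact enumeration at the
  feature level instead.
* The PBPK `others` compartment is a closure device with its own fitted
  partition coefficient; per-gram vs per-mL tissue concentration
  conversion is the curator's responsibility upstream of the CSV contract.
* Exposure-time dose-response is exposed as a fit, not fixed constants;
  its functional form on real data is model- and corpus-dependent.
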