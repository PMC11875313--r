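# nanotox

Machine-learning prediction of inorganic nanoparticle toxicity, in vitro
and in vivo, with a PBPK exposure bridge.

## Who this is for

Nanomedicine and nanosafety researchers who need to (i) harmonize
heterogeneous cytotoxicity records into a single analyzable table,
(ii) train and honestly evaluate classifiers for the safe/cytotoxic
endpoint, (iii) understand *which* physicochemical properties drive the
predictions, and (iv) extend the same classifier to organ-specific in vivo
toxicity when only biodistribution time series and dosing metadata are
available.

## What it does

**Harmonize.** Raw records (size nm, concentration ug/mL, exposure h,
composition, coating, shape, zeta potential mV, species, organ, cell
class, % viability) are curated with fixed rules — viability >= 70% is
safe (0), below is cytotoxic (1) per ISO 10993-5; zeta is classed positive
(> 10 mV) / negative (< -10 mV) / neutral / not determined; missing
coating and shape impute to `Unmodified` and `Sphere`; 1.5 x IQR outlier
screening on the log10 scale — then log10-transformed and one-hot encoded
(least frequent level dropped) into a schema-tracked design matrix.

**Train.** 10-fold nested cross-validation with inner-loop grid search
maximizing PR-AUC over a panel of tree ensembles (three gradient-boosting
configurations, random forest, extremely randomized trees), hold-out
early stopping for boosters (log-loss, patience 50, up to 5000 rounds),
per-fold winner consolidation, final refit, and an F1-maximizing decision
threshold. A logistic meta-learner stacks the base models on strictly
out-of-fold probabilities.

**Explain.** Exact Shapley attributions of the predicted probability
(polynomial tree-path algorithm for forests, exact subset enumeration per
original feature otherwise), one-hot groups aggregated by signed sum,
Spearman rank consensus across models, per-level median summaries for
categorical features, partial dependence curves with four-parameter
logistic (concentration) and power-law (size) fits, and SHAP-ranked
iterative feature reduction with an explicit plateau rule.

**Bridge to in vivo.** A six-compartment minimal PBPK model (plasma,
liver, spleen, lungs, kidneys, others; perfusion-limited transport,
first-order biliary and urinary excretion, depot absorption for non-IV
routes) is calibrated to organ biodistribution series by multi-start
Levenberg-Marquardt in log-parameter space. Studies with Pearson R > 0.9
between fit and data are accepted, and the time-averaged exposure

&nbsp;&nbsp;&nbsp;&nbsp;C-hat_i = AUC_i(0 - t_tox) / t_tox

replaces the administered-concentration feature, after which the identical
training machinery produces organ-specific in vivo predictions.

**Synthesize.** A generator with planted, known ground truth (logistic
effect model over realistic marginals; study-level PBPK parameters for
biodistribution panels) makes every stage testable end to end and reports
the Bayes-achievable PR-AUC ceiling alongside each dataset.

## Worked example

```r
library(nanotox)

ds <- gen_invitro(synth_config(n = 2000, seed = 3))
ds
#> Synthetic in vitro dataset: 2000 records, 37% toxic
#>   Bayes-achievable PR-AUC (true probabilities): 0.8874

mat   <- encode(harmonize(ds$records))
parts <- split_dataset(mat, test_fraction = 0.2, seed = 3)

fit <- nanotox_train(parts$train, spec_gbt("depthwise"),
                     grid = list(max_depth = c(3, 6), eta = c(0.1, 0.3),
                                 max_rounds = 400, patience = 25),
                     k_outer = 5, k_inner = 3, seed = 3)
fit
#> nanotox model (gbt_depthwise)
#>   final hyperparameters: max_depth=3, eta=0.1, max_rounds=400, patience=25
#>   operating threshold: 0.499
#>   outer-fold PR-AUC: 0.8628

metric_report(parts$test$y, predict(fit, parts$test), fit$threshold)
#> Classification report (n = 400, threshold = 0.499)
#>   pr_auc             0.9030
#>   roc_auc            0.9343
#>   sensitivity        0.7770
#>   ...

att <- attribute(function(x) fit$spec$predict_prob(fit$model, x),
                 parts$test, n_background = 64, seed = 3)
group_and_rank(att)
#> Feature importance (mean |attribution|):
#>   conc_ug_per_ml   0.29833
#>   time_h           0.02571
#>   composition      0.02569
#>   size_nm          0.02018
#>   ...
```

Reading the numbers: the nested-CV outer PR-AUC (0.863) sits close to the
generator's Bayes ceiling (0.887) — the model has recovered essentially all
learnable signal — and the attribution ranking identifies the planted
dominant driver (concentration) with the remaining effects an order of
magnitude smaller, matching how the labels were generated.

The PBPK stage follows the same pattern:

```r
phys  <- physiology_mouse()
truth <- pbpk_params(P = c(liver = 20, spleen = 8, lungs = 2,
                           kidneys = 1.5, others = 0.4),
                     k_bile = 0.05, k_urine = 0.1)
obs <- gen_biodist(truth, phys, pbpk_doses("IV", 200), noise_cv = 0.1, seed = 1)
fit <- pbpk_fit(obs, phys, pbpk_doses("IV", 200), log_residuals = TRUE, seed = 3)
accept_fit(fit)          # TRUE iff Pearson R > 0.9
exposure(fit, "liver", t_tox = 24)
```

A thin command-line front end over these functions lives at
`inst/cli/nanotox.R` (subcommands `synth`, `harmonize`, `train`,
`evaluate`, `pbpk-fit`, `pipeline`), and `run_pipeline()` orchestrates the
whole flow with cached, resumable, provenance-stamped stage outputs.

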