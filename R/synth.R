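# Marginal distributions emulating the curated in vitro corpus: continuous
# descriptors are log-uniform over the published ranges; categorical
# proportions follow the published shares, with the remainder of each
# feature split over plausible minor levels.
default_marginals <- function() {
  list(
    size_nm = c(1.5, 1000),
    conc_ug_per_ml = c(5e-4, 3.2e6),
    time_h = c(0.083, 336),
    composition = c(SiO2 = 0.411, Ag = 0.2269, ZnO = 0.1451, TiO2 = 0.08,
                    Au = 0.05, Fe3O4 = 0.04, CuO = 0.02, CeO2 = 0.015,
                    Cd = 0.012),
    coating = c(Unmodified = 0.7457, PEG = 0.10, Citrate = 0.06, PVP = 0.05,
                Lipid = 0.0443),
    shape = c(Sphere = 0.8962, Rod = 0.06, Cube = 0.0438),
    zeta_class = c(negative = 0.4315, not_determined = 0.428,
                   positive = 0.0816, neutral = 0.0589),
    species = c(human = 0.7527, mouse = 0.15, rat = 0.0973),
    organ = c(lungs = 0.1871, liver = 0.16, kidneys = 0.12, brain = 0.10,
              breast = 0.09, colon = 0.09, skin = 0.0879, blood = 0.0833,
              heart = 0.0817),
    cell_class = c(cell_line = 0.87, primary = 0.13))
}

# Ground-truth logistic effect model. Coefficients act on centered log10
# continuous features (centers = midpoints of the log-uniform ranges) and on
# categorical offsets; signs follow the known toxicology: concentration and
# exposure time increase toxicity, size decreases it, cationic particles and
# heavy-metal compositions are riskier, PEGylation is protective.
default_effects <- function() {
  list(
    conc = 0.9, size = -0.45, time = 0.3,
    zeta = c(positive = 0.5),
    composition = c(Cd = 1.0, Ag = 0.6, ZnO = 0.5, CuO = 0.5,
                    CeO2 = -0.5, Fe3O4 = -0.4),
    coating = c(PEG = -0.2),
    label_flip = 0)
}

#' Configuration for the synthetic in vitro generator
#'
#' Bundles sample size, seed, marginal distributions and the planted
#' logistic effect model. Defaults emulate the published corpus: continuous
#' features log-uniform over the stated ranges, categorical shares as
#' reported, toxic prevalence calibrated to 37.3%.
#'
#' @param n Sample count.
#' @param seed Integer seed.
#' @param target_prevalence Toxic fraction the intercept is calibrated to.
#' @param marginals Marginal specification (see `default_marginals` in the
#'   source); partial overrides are merged over the defaults.
#' @param effects Effect model (see `default_effects`); partial overrides
#'   merged over the defaults. Set coefficients to zero (and drop offsets)
#'   to control which features are informative.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n = 5000, seed = 3, target_prevalence = 0.373,
                         marginals = list(), effects = list()) {
  m <- modifyList(default_marginals(), marginals)
  e <- modifyList(default_effects(), effects)
  for (f in c("composition", "coating", "shape", "zeta_class", "species",
              "organ", "cell_class")) {
    if (abs(sum(m[[f]]) - 1) > 1e-6)
      stop("proportions for '", f, "' must sum to 1")
  }
  for (f in c("size_nm", "conc_ug_per_ml", "time_h")) {
    if (any(m[[f]] <= 0)) stop("range for '", f, "' must be positive")
  }
  structure(list(n = n, seed = seed, target_prevalence = target_prevalence,
                 marginals = m, effects = e),
            class = "synth_config")
}

# Internal: the linear predictor of the planted model, minus the intercept.
truth_eta <- function(records, marginals, effects) {
  center <- function(range) mean(log10(range))
  off <- function(vec, lev) {
    o <- vec[lev]; o[is.na(o)] <- 0; unname(o)
  }
  eta <- effects$conc * (log10(records$conc_ug_per_ml) - center(marginals$conc_ug_per_ml)) +
    effects$size * (log10(records$size_nm) - center(marginals$size_nm)) +
    effects$time * (log10(records$time_h) - center(marginals$time_h))
  contrib <- data.frame(
    conc = effects$conc * (log10(records$conc_ug_per_ml) - center(marginals$conc_ug_per_ml)),
    size = effects$size * (log10(records$size_nm) - center(marginals$size_nm)),
    time = effects$time * (log10(records$time_h) - center(marginals$time_h)),
    zeta = off(effects$zeta, records$zeta_class),
    composition = off(effects$composition, records$composition),
    coating = off(effects$coating, records$coating))
  list(eta = rowSums(contrib), contrib = contrib)
}

# Internal: intercept such that the mean logistic probability over the drawn
# covariates equals the target prevalence (bisection; the mean is monotone
# in the intercept).
calibrate_intercept <- function(eta, target) {
  f <- function(a) mean(plogis(eta + a)) - target
  lo <- -20; hi <- 20
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Generate synthetic in vitro cytotoxicity records with known ground truth
#'
#' Draws physicochemical descriptors from the configured marginals and
#' toxicity labels from the planted logistic model, whose intercept is
#' calibrated by bisection so the expected toxic fraction matches the
#' configured prevalence. A viability percentage consistent with each label
#' is synthesized so the curation rules reproduce the labels exactly. The
#' returned truth table carries each sample's generating probability and
#' per-feature contribution, from which the Bayes-achievable PR-AUC (the
#' ceiling for any classifier) can be computed.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_invitro`: `records` (data frame ready for
#'   [harmonize()]), `truth` (probabilities + contributions), `intercept`,
#'   `bayes_pr_auc`.
#' @export
gen_invitro <- function(config = synth_config()) {
  m <- config$marginals
  with_seed(config$seed, {
    n <- config$n
    logu <- function(range) 10^runif(n, log10(range[1]), log10(range[2]))
    cat_draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    rec <- data.frame(
      row_id = paste0("s", seq_len(n)),
      size_nm = logu(m$size_nm),
      conc_ug_per_ml = logu(m$conc_ug_per_ml),
      time_h = logu(m$time_h),
      composition = cat_draw(m$composition),
      coating = cat_draw(m$coating),
      shape = cat_draw(m$shape),
      zeta_class = cat_draw(m$zeta_class),
      species = cat_draw(m$species),
      organ = cat_draw(m$organ),
      cell_class = cat_draw(m$cell_class),
      stringsAsFactors = FALSE)
    tr <- truth_eta(rec, m, config$effects)
    a <- calibrate_intercept(tr$eta, config$target_prevalence)
    p <- plogis(a + tr$eta)
    label <- rbinom(n, 1, p)
    flip <- config$effects$label_flip
    if (flip > 0) {
      do_flip <- runif(n) < flip
      label[do_flip] <- 1L - label[do_flip]
    }
    rec$viability_pct <- ifelse(label == 1, runif(n, 0, 69.9),
                                runif(n, 70, 120))
    rec$label <- as.integer(label)
    truth <- cbind(data.frame(row_id = rec$row_id, p = p, label = rec$label),
                   tr$contrib)
    structure(list(records = rec, truth = truth, intercept = a,
                   bayes_pr_auc = pr_curve(rec$label, p)$area,
                   config = config),
              class = "synth_invitro")
  })
}

#' @export
print.synth_invitro <- function(x, ...) {
  cat("Synthetic in vitro dataset: ", nrow(x$records), " records, ",
      round(100 * mean(x$records$label), 1), "% toxic\n",
      "  Bayes-achievable PR-AUC (true probabilities): ",
      format(x$bayes_pr_auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Generate a sparse noisy biodistribution panel from a known PBPK model
#'
#' Simulates the PBPK model under the true parameters, samples the stated
#' number of log-spaced time points, and applies multiplicative lognormal
#' noise with the given coefficient of variation (mean-corrected, so the
#' expected noisy value equals the simulated one).
#'
#' @param true_params A [pbpk_params()].
#' @param physiology A [pbpk_physiology()].
#' @param doses A [pbpk_doses()] table.
#' @param n_timepoints Number of sampled times (>= 3).
#' @param t_range Sampling window (h), log-spaced.
#' @param organs Organs observed.
#' @param noise_cv Lognormal coefficient of variation (0 = noiseless).
#' @param seed Integer seed.
#' @return Data frame `organ`, `time_h`, `conc_ug_per_ml` suitable for
#'   [pbpk_fit()], with the noiseless simulation in the `true_conc` column.
#' @export
gen_biodist <- function(true_params, physiology, doses, n_timepoints = 8,
                        t_range = c(0.25, 48), organs = PBPK_ORGANS,
                        noise_cv = 0.1, seed = 3) {
  if (n_timepoints < 3) stop("need at least 3 distinct time points")
  tt <- 10^seq(log10(t_range[1]), log10(t_range[2]),
               length.out = n_timepoints)
  sim <- pbpk_simulate(true_params, physiology, doses, c(0, tt))
  obs <- expand.grid(organ = organs, time_h = tt, stringsAsFactors = FALSE)
  obs$true_conc <- sim$conc[cbind(match(obs$time_h, sim$time),
                                  match(obs$organ, colnames(sim$conc)))]
  obs$conc_ug_per_ml <- with_seed(seed, {
    if (noise_cv > 0) {
      sigma <- sqrt(log(1 + noise_cv^2))
      obs$true_conc * exp(rnorm(nrow(obs), -sigma^2 / 2, sigma))
    } else obs$true_conc
  })
  obs
}

#' Generate labeled in vivo toxicity records from exposure metrics
#'
#' Draws organ-level toxicity labels from a logistic model in the
#' log10 time-averaged exposure plus composition and coating offsets. The
#' intercept is calibrated so the expected toxic fraction matches
#' `target_prevalence` (default 16.2%, the in vivo class balance).
#'
#' @param exposures Data frame with columns `c_hat`, `composition`,
#'   `coating` (one row per record; other columns pass through).
#' @param b_chat Slope on centered log10(c_hat).
#' @param effects Composition/coating offsets; defaults shared with
#'   [gen_invitro()].
#' @param target_prevalence Calibration target for the toxic fraction.
#' @param seed Integer seed.
#' @return The input with `p` (true probability) and `label` columns added;
#'   the Bayes-achievable PR-AUC is attached as attribute `bayes_pr_auc`.
#' @export
gen_invivo_tox <- function(exposures, b_chat = 1.2, effects = NULL,
                           target_prevalence = 0.162, seed = 3) {
  e <- effects %||% default_effects()
  off <- function(vec, lev) { o <- vec[lev]; o[is.na(o)] <- 0; unname(o) }
  lc <- log10(pmax(exposures$c_hat, 1e-12))
  eta <- b_chat * (lc - median(lc)) +
    off(e$composition, exposures$composition) +
    off(e$coating, exposures$coating)
  a <- calibrate_intercept(eta, target_prevalence)
  p <- plogis(a + eta)
  out <- exposures
  out$p <- p
  out$label <- with_seed(seed, rbinom(length(p), 1, p))
  attr(out, "bayes_pr_auc") <- if (length(unique(out$label)) == 2)
    pr_curve(out$label, p)$area else NA_real_
  attr(out, "intercept") <- a
  out
}

#' Generate a panel of synthetic in vivo biodistribution studies
#'
#' Convenience generator for the full in vivo bridge: each study is one
#' nanoparticle formulation dosed intravenously in a mouse, with its own
#' random true PBPK parameters and a noisy sparse biodistribution panel;
#' records are study x organ x assessment-time combinations carrying the
#' formulation's physicochemical descriptors.
#'
#' @param n_studies Number of studies.
#' @param physiology A [pbpk_physiology()].
#' @param n_timepoints,noise_cv Passed to [gen_biodist()].
#' @param organs Target organs generating records.
#' @param t_tox Assessment times (h) generating records.
#' @param seed Integer seed.
#' @return List of class `synth_invivo`: `studies` (per-study metadata and
#'   true parameters), `biodist` (named list of observation panels),
#'   `records` (record table without labels; see [gen_invivo_tox()]).
#' @export
gen_invivo_studies <- function(n_studies = 33, physiology = physiology_mouse(),
                               n_timepoints = 8, noise_cv = 0.1,
                               organs = c("liver", "spleen", "kidneys", "lungs"),
                               t_tox = c(24, 48), seed = 3) {
  comps <- c(Au = 0.428, Fe3O4 = 0.231, Ag = 0.091, SiO2 = 0.15, ZnO = 0.10)
  with_seed(seed, {
    studies <- data.frame(
      study_id = paste0("study", seq_len(n_studies)),
      size_nm = 10^runif(n_studies, log10(1.2), log10(310)),
      composition = sample(names(comps), n_studies, TRUE, prob = comps),
      coating = sample(c("Unmodified", "PEG", "Citrate"), n_studies, TRUE,
                       prob = c(0.4205, 0.2744, 0.3051)),
      shape = sample(c("Sphere", "Rod"), n_studies, TRUE, prob = c(0.9, 0.1)),
      zeta_class = sample(c("negative", "neutral", "positive",
                            "not_determined"), n_studies, TRUE,
                          prob = c(0.45, 0.15, 0.10, 0.30)),
      species = "mouse",
      dose_ug = 10^runif(n_studies, 2, 3),
      stringsAsFactors = FALSE)
    true_params <- lapply(seq_len(n_studies), function(i) {
      pbpk_params(P = setNames(10^runif(5, -1, 1.7), PBPK_ORGANS),
                  k_bile = 10^runif(1, -2, -0.3),
                  k_urine = 10^runif(1, -2, -0.3))
    })
    names(true_params) <- studies$study_id
    biodist <- lapply(seq_len(n_studies), function(i) {
      gen_biodist(true_params[[i]], physiology,
                  pbpk_doses("IV", studies$dose_ug[i]),
                  n_timepoints = n_timepoints, noise_cv = noise_cv,
                  seed = child_seed(seed, i))
    })
    names(biodist) <- studies$study_id
    records <- merge(studies,
                     expand.grid(study_id = studies$study_id, organ = organs,
                                 time_h = t_tox, stringsAsFactors = FALSE),
                     by = "study_id")
    structure(list(studies = studies, true_params = true_params,
                   biodist = biodist, records = records,
                   physiology = physiology),
              class = "synth_invivo")
  })
}
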