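#' Define a classifier for the training harness
#'
#' A classifier spec is the contract the nested cross-validation harness,
#' stacking ensemble and feature-reduction loop operate over: a factory taking
#' a hyperparameter list and returning a fitted model, plus a probability
#' scorer. Any learner satisfying this contract is pluggable.
#'
#' @param name Short token naming the learner.
#' @param fit `function(x, y, params, seed)` returning a fitted model; `x` is a
#'   numeric matrix, `y` an integer 0/1 vector.
#' @param predict_prob `function(model, x)` returning probability-of-toxic in
#'   \[0, 1\].
#' @param default_grid Named list of hyperparameter candidate vectors.
#' @param supports_early_stopping Whether the learner monitors hold-out
#'   log-loss during boosting.
#' @param fit_es Optional `function(x, y, x_val, y_val, params, max_rounds,
#'   patience, seed)` returning `list(model, best_round)`; required when
#'   `supports_early_stopping` is `TRUE`.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, fit, predict_prob, default_grid = list(),
                            supports_early_stopping = FALSE, fit_es = NULL) {
  if (supports_early_stopping && is.null(fit_es))
    stop("early-stopping spec needs a fit_es function")
  structure(list(name = name, fit = fit, predict_prob = predict_prob,
                 default_grid = default_grid,
                 supports_early_stopping = supports_early_stopping,
                 fit_es = fit_es),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier spec '", x$name, "'",
      if (x$supports_early_stopping) " (early stopping)", "\n", sep = "")
  invisible(x)
}

xgb_params <- function(params, variant, seed) {
  p <- list(objective = "binary:logistic", eval_metric = "logloss",
            max_depth = params$max_depth %||% 6,
            eta = params$eta %||% 0.1,
            subsample = params$subsample %||% 1,
            nthread = 1, seed = seed %||% 3)
  if (variant == "lossguide") {
    p$tree_method <- "hist"; p$grow_policy <- "lossguide"
    p$max_leaves <- params$max_leaves %||% 31
  } else if (variant == "exact") {
    p$tree_method <- "exact"
  } else {
    p$tree_method <- "hist"; p$grow_policy <- "depthwise"
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gradient-boosted tree classifier specs
#'
#' Three distinct boosting configurations built on xgboost: `"depthwise"`
#' (histogram splits, level-wise growth), `"lossguide"` (histogram splits,
#' leaf-wise growth in the style of LightGBM), and `"exact"` (exact greedy
#' split enumeration in the style of a classic gradient boosting classifier).
#' All three monitor log-loss on a 10% stratified hold-out and stop early
#' after `patience` rounds without improvement (defaults 5000 rounds max,
#' patience 50).
#'
#' @param variant One of `"depthwise"`, `"lossguide"`, `"exact"`.
#' @return A `classifier_spec`.
#' @export
spec_gbt <- function(variant = c("depthwise", "lossguide", "exact")) {
  variant <- match.arg(variant)
  fit_es <- function(x, y, x_val, y_val, params, max_rounds, patience, seed) {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    dval <- xgboost::xgb.DMatrix(x_val, label = y_val)
    booster <- xgboost::xgb.train(
      params = xgb_params(params, variant, seed), data = dtrain,
      nrounds = max_rounds, evals = list(holdout = dval),
      early_stopping_rounds = patience, verbose = 0)
    best <- tryCatch(xgboost::xgb.attr(booster, "best_iteration"),
                     error = function(e) NULL)
    best <- suppressWarnings(as.integer(best))
    if (is.na(best) || length(best) == 0) best <- max_rounds
    list(model = booster, best_round = best)
  }
  classifier_spec(
    name = paste0("gbt_", variant),
    fit = function(x, y, params = list(), seed = 3) {
      hold <- stratified_holdout(y, params$holdout_fraction %||% 0.10, seed)
      res <- fit_es(x[-hold, , drop = FALSE], y[-hold],
                    x[hold, , drop = FALSE], y[hold], params,
                    params$max_rounds %||% 5000, params$patience %||% 50, seed)
      res$model
    },
    predict_prob = function(model, x) {
      as.numeric(predict(model, xgboost::xgb.DMatrix(x)))
    },
    default_grid = list(max_depth = c(3, 6), eta = c(0.1, 0.3)),
    supports_early_stopping = TRUE,
    fit_es = fit_es)
}

ranger_spec <- function(name, splitrule) {
  classifier_spec(
    name = name,
    fit = function(x, y, params = list(), seed = 3) {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))   # ranger dislikes '=' in names
      df$.y <- factor(y, levels = c(0, 1))
      mtry <- max(1L, floor((params$mtry_frac %||% 0.33) * ncol(x)))
      ranger::ranger(
        dependent.variable.name = ".y", data = df, probability = TRUE,
        num.trees = params$num_trees %||% 100, mtry = mtry,
        min.node.size = params$min_node_size %||% 5,
        splitrule = splitrule,
        num.random.splits = 1,
        replace = splitrule != "extratrees",
        sample.fraction = if (splitrule == "extratrees") 1 else 0.632,
        seed = seed %||% 3, num.threads = 1)
    },
    predict_prob = function(model, x) {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      as.numeric(predict(model, data = df, num.threads = 1)$predictions[, "1"])
    },
    default_grid = list(mtry_frac = c(0.33, 0.6), min_node_size = c(1, 5)))
}

#' Random forest classifier spec
#'
#' Bootstrap-aggregated classification trees (ranger backend, probability
#' forest: the score is the fraction-weighted class frequency averaged over
#' trees, so the ensemble probability is the mean of per-tree leaf values).
#' @return A `classifier_spec`.
#' @export
spec_random_forest <- function() ranger_spec("random_forest", "gini")

#' Extremely randomized trees classifier spec
#'
#' Like a random forest but with random split points and no bootstrap
#' resampling (ranger `extratrees` split rule on the full sample).
#' @return A `classifier_spec`.
#' @export
spec_extra_trees <- function() ranger_spec("extra_trees", "extratrees")

#' The default base-learner panel
#'
#' Five tree-ensemble learners: three gradient-boosting configurations
#' (depth-wise, leaf-wise, exact-split) plus random forest and extremely
#' randomized trees.
#' @return Named list of `classifier_spec` objects.
#' @export
default_specs <- function() {
  list(gbt_depthwise = spec_gbt("depthwise"),
       gbt_lossguide = spec_gbt("lossguide"),
       gbt_exact = spec_gbt("exact"),
       random_forest = spec_random_forest(),
       extra_trees = spec_extra_trees())
}

# Internal: indices of a stratified holdout (used for early-stopping
# monitoring). Errors if the holdout would be under 10 rows.
stratified_holdout <- function(y, fraction, seed) {
  n_hold <- round(length(y) * fraction)
  if (n_hold < 10) stop("holdout would have ", n_hold,
                        " rows (< 10); use more training data")
  with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(idx) {
      idx <- sample(idx)
      idx[seq_len(max(1L, round(length(idx) * fraction)))]
    }), use.names = FALSE)
  })
}
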