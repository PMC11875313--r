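#' Stratified fold assignment
#'
#' Assigns rows to `k` cross-validation folds so that fold sizes differ by at
#' most one and each fold's class prevalence stays within one count of the
#' global prevalence. Deterministic for a given seed.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k, seed = 3) {
  labels <- as.integer(labels)
  if (k < 2) stop("cross-validation needs at least 2 folds")
  if (min(table(labels)) < k) stop("each class must have at least k rows")
  folds <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      # rotate the fold sequence between classes so overall sizes stay within 1
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  folds
}

# Internal: expand a named list of candidate vectors into a list of parameter
# lists, in expand.grid order (first hyperparameter varying fastest).
grid_points <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Inner-loop grid search maximizing PR-AUC
#'
#' Evaluates every grid point by `k_inner`-fold stratified cross-validation
#' and returns the point with the highest mean held-out-fold PR-AUC. Ties go
#' to the earlier point in grid order. A grid point whose fit fails is skipped
#' with a warning; an error is raised only if every point fails.
#'
#' @param x Numeric design matrix.
#' @param y Binary labels.
#' @param spec A [classifier_spec()].
#' @param grid Named list of hyperparameter candidate vectors.
#' @param k_inner Number of inner folds.
#' @param seed Integer seed.
#' @return List with `best_params`, `best_score`, `oof_scores` (pooled
#'   out-of-fold probabilities for the winning point), `folds`, and a
#'   `results` data frame of mean PR-AUC per grid point.
#' @export
inner_search <- function(x, y, spec, grid, k_inner = 5, seed = 3) {
  points <- grid_points(grid)
  if (length(points) == 0) stop("empty hyperparameter grid")
  folds <- stratified_folds(y, k_inner, seed)
  scores <- rep(NA_real_, length(points))
  oof_all <- vector("list", length(points))
  for (g in seq_along(points)) {
    oof <- rep(NA_real_, length(y))
    ok <- TRUE
    for (f in seq_len(k_inner)) {
      tr <- folds != f
      fit <- tryCatch(
        spec$fit(x[tr, , drop = FALSE], y[tr], points[[g]],
                 seed = child_seed(seed, f)),   # same seed across grid points
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("grid point ", g, " failed in fold ", f, ": ",
                conditionMessage(fit))
        ok <- FALSE
        break
      }
      oof[!tr] <- spec$predict_prob(fit, x[!tr, , drop = FALSE])
    }
    if (ok) {
      scores[g] <- mean(vapply(seq_len(k_inner), function(f) {
        pr_curve(y[folds == f], oof[folds == f])$area
      }, numeric(1)))
      oof_all[[g]] <- oof
    }
  }
  if (all(is.na(scores))) stop("every grid point failed to fit")
  best <- which.max(scores)   # first maximum wins ties
  list(best_params = points[[best]], best_score = scores[best],
       oof_scores = oof_all[[best]], folds = folds,
       results = data.frame(point = seq_along(points), mean_pr_auc = scores))
}

#' Nested cross-validation
#'
#' The outer loop estimates generalization: for each of `k_outer` stratified
#' outer folds, the inner loop runs [inner_search()] on the remaining folds,
#' the winning hyperparameters are refit on all outer-training rows, and the
#' held-out fold is scored. No row ever appears in both the training and the
#' evaluation side of the same iteration.
#'
#' @param mat A `nanotox_matrix` (typically the training partition from
#'   [split_dataset()]).
#' @param spec A [classifier_spec()].
#' @param grid Hyperparameter grid; defaults to the spec's `default_grid`.
#' @param k_outer,k_inner Fold counts for the two loops.
#' @param seed Integer seed.
#' @return Object of class `nanotox_ncv`: per-fold best parameters, metric
#'   reports and scores; `consolidated_grid`; row-id bookkeeping for leakage
#'   audits.
#' @export
nested_cv <- function(mat, spec, grid = NULL, k_outer = 10, k_inner = 5,
                      seed = 3) {
  grid <- grid %||% spec$default_grid
  y <- mat$y
  folds <- stratified_folds(y, k_outer, seed)
  fold_results <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    tr <- folds != f
    search <- inner_search(mat$x[tr, , drop = FALSE], y[tr], spec, grid,
                           k_inner, child_seed(seed, f))
    fit <- spec$fit(mat$x[tr, , drop = FALSE], y[tr], search$best_params,
                    seed = child_seed(seed, 1000 + f))
    sc <- spec$predict_prob(fit, mat$x[!tr, , drop = FALSE])
    fold_results[[f]] <- list(
      fold = f, best_params = search$best_params,
      inner_pr_auc = search$best_score,
      report = metric_report(y[!tr], sc),
      scores = sc, test_row_ids = mat$row_ids[!tr],
      train_row_ids = mat$row_ids[tr])
  }
  structure(list(spec_name = spec$name, folds = folds,
                 fold_results = fold_results,
                 consolidated_grid = consolidate_grid(
                   lapply(fold_results, `[[`, "best_params")),
                 outer_pr_auc = vapply(fold_results,
                                       function(r) r$report$pr_auc, numeric(1)),
                 seed = seed),
            class = "nanotox_ncv")
}

#' @export
print.nanotox_ncv <- function(x, ...) {
  cat("Nested cross-validation (", length(x$fold_results), " outer folds, ",
      x$spec_name, ")\n", sep = "")
  cat(sprintf("  outer PR-AUC: mean %.4f (range %.4f-%.4f)\n",
              mean(x$outer_pr_auc), min(x$outer_pr_auc), max(x$outer_pr_auc)))
  rec <- vapply(x$fold_results, function(r) r$report$sensitivity, numeric(1))
  cat(sprintf("  outer recall: mean %.4f\n", mean(rec)))
  invisible(x)
}

#' @export
summary.nanotox_ncv <- function(object, ...) {
  df <- do.call(rbind, lapply(object$fold_results, function(r) {
    data.frame(fold = r$fold, pr_auc = r$report$pr_auc,
               roc_auc = r$report$roc_auc, recall = r$report$sensitivity,
               precision = r$report$precision, f1 = r$report$f1)
  }))
  df
}

#' Consolidate per-fold winning hyperparameters into a refined grid
#'
#' For each hyperparameter, the refined candidate list is the set of values
#' chosen by any outer fold, deduplicated and order-preserving; its cartesian
#' product is therefore never larger than the original grid's.
#'
#' @param per_fold_best List of per-fold winning parameter lists.
#' @return Named list of candidate vectors.
#' @export
consolidate_grid <- function(per_fold_best) {
  if (length(per_fold_best) == 0) stop("no fold results to consolidate")
  params <- names(per_fold_best[[1]])
  out <- lapply(params, function(p) {
    unique(unlist(lapply(per_fold_best, `[[`, p)))
  })
  setNames(out, params)
}

#' Final refit on the full training partition
#'
#' Runs an inner-CV search over the refined grid on all training rows, refits
#' the winner on the full partition, and tunes the operating threshold by
#' maximizing F1 on the pooled held-out-fold scores of the winning point (so
#' the threshold never sees in-fold predictions).
#'
#' @inheritParams nested_cv
#' @param refined_grid Grid from [consolidate_grid()].
#' @return List with `model`, `params`, `threshold`, `search`.
#' @export
fit_final <- function(mat, spec, refined_grid, k_inner = 5, seed = 3) {
  search <- inner_search(mat$x, mat$y, spec, refined_grid, k_inner,
                         child_seed(seed, 7777))
  model <- spec$fit(mat$x, mat$y, search$best_params,
                    seed = child_seed(seed, 8888))
  threshold <- tune_threshold(mat$y, search$oof_scores)
  list(model = model, params = search$best_params, threshold = threshold,
       search = search)
}

#' Fit a boosting learner with hold-out early stopping
#'
#' Splits off a stratified hold-out (default 10% of rows), monitors hold-out
#' log-loss during boosting, and stops at the first round whose preceding
#' `patience` rounds produced no improvement, up to `max_rounds`. The
#' returned model predicts with the best round.
#'
#' @param spec A [classifier_spec()] with `supports_early_stopping = TRUE`.
#' @param x,y Training matrix and binary labels.
#' @param params Hyperparameters passed to the learner.
#' @param max_rounds Maximum boosting rounds (default 5000).
#' @param patience Rounds without improvement before stopping (default 50).
#' @param holdout_fraction Fraction of rows monitored (default 0.10).
#' @param seed Integer seed.
#' @return List with `model` and `best_round`.
#' @export
early_stopping_fit <- function(spec, x, y, params = list(), max_rounds = 5000,
                               patience = 50, holdout_fraction = 0.10,
                               seed = 3) {
  if (!isTRUE(spec$supports_early_stopping))
    stop("spec '", spec$name, "' does not support early stopping")
  hold <- stratified_holdout(y, holdout_fraction, seed)
  spec$fit_es(x[-hold, , drop = FALSE], y[-hold],
              x[hold, , drop = FALSE], y[hold],
              params, max_rounds, patience, seed)
}

#' Train a toxicity classifier end to end
#'
#' The package's main fitting function: nested cross-validation for an
#' unbiased performance estimate, consolidation of the per-fold winning
#' hyperparameters into a refined grid, and a final refit on the full
#' training partition with an F1-tuned operating threshold.
#'
#' @inheritParams nested_cv
#' @return Object of class `nanotox_model` with `print`, `summary` and
#'   [predict.nanotox_model()] methods.
#' @export
nanotox_train <- function(mat, spec, grid = NULL, k_outer = 10, k_inner = 5,
                          seed = 3) {
  ncv <- nested_cv(mat, spec, grid, k_outer, k_inner, seed)
  final <- fit_final(mat, spec, ncv$consolidated_grid, k_inner, seed)
  structure(list(spec = spec, ncv = ncv, model = final$model,
                 params = final$params, threshold = final$threshold,
                 schema = mat$schema, columns = colnames(mat$x), seed = seed),
            class = "nanotox_model")
}

#' Predict toxicity probabilities or labels
#'
#' @param object A `nanotox_model`.
#' @param newdata A `nanotox_matrix` or plain numeric matrix with the
#'   training columns.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 calls at the
#'   tuned threshold.
#' @param ... Unused.
#' @export
predict.nanotox_model <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "nanotox_matrix")) newdata$x else as.matrix(newdata)
  cols <- object$columns
  if (!is.null(colnames(x)) && all(cols %in% colnames(x))) {
    x <- x[, cols, drop = FALSE]
  } else if (ncol(x) != length(cols)) {
    stop("newdata columns do not match the training schema")
  }
  p <- object$spec$predict_prob(object$model, x)
  if (type == "prob") p else as.integer(p >= object$threshold)
}

#' @export
print.nanotox_model <- function(x, ...) {
  cat("nanotox model (", x$spec$name, ")\n", sep = "")
  cat("  final hyperparameters: ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n  operating threshold: ", format(x$threshold, digits = 3),
      "\n  outer-fold PR-AUC: ", format(mean(x$ncv$outer_pr_auc), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.nanotox_model <- function(object, ...) {
  list(spec = object$spec$name, params = object$params,
       threshold = object$threshold, outer_folds = summary(object$ncv))
}
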