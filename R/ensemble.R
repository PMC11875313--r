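# Ridge-penalized logistic regression by iteratively reweighted least
# squares. The intercept is unpenalized. A small L2 penalty keeps the meta
# fit defined when base-model outputs are collinear or constant.
ridge_logistic <- function(x, y, lambda = 1e-3, max_iter = 100, tol = 1e-10) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  beta <- rep(0, ncol(x))
  pen <- diag(c(0, rep(lambda, ncol(x) - 1)), ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(x, w * x) + pen, crossprod(x, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Fit a stacking ensemble with a logistic meta-learner
#'
#' Stacks the probability outputs of a panel of base classifiers under a
#' (mildly ridge-penalized) logistic regression meta-model. The meta-learner
#' is trained exclusively on out-of-fold base probabilities: each base is
#' refit `k_meta` times over a stratified fold split, so the meta-training
#' row for a sample always comes from a base model that never saw that
#' sample. The final base models are then refit on all training rows.
#'
#' @param mat A `nanotox_matrix` with labels.
#' @param base_specs List of [classifier_spec()] objects (>= 1; a single base
#'   gives a degenerate stack whose scores are a monotone transform of the
#'   base scores).
#' @param base_params Optional list (parallel to `base_specs`) of
#'   hyperparameter lists; defaults to each spec's defaults.
#' @param k_meta Folds for the out-of-fold construction.
#' @param lambda Ridge penalty on the meta coefficients.
#' @param seed Integer seed.
#' @return Object of class `nanotox_stack`.
#' @export
fit_stack <- function(mat, base_specs, base_params = NULL, k_meta = 5,
                      lambda = 1e-3, seed = 3) {
  if (length(base_specs) < 1) stop("need at least one base spec")
  y <- mat$y
  if (is.null(base_params)) base_params <- lapply(base_specs, function(s) list())
  folds <- stratified_folds(y, k_meta, seed)
  oof <- matrix(NA_real_, nrow = length(y), ncol = length(base_specs))
  colnames(oof) <- vapply(base_specs, `[[`, character(1), "name")
  oof_rows <- character(length(y))   # which fold produced each meta row
  for (b in seq_along(base_specs)) {
    spec <- base_specs[[b]]
    for (f in seq_len(k_meta)) {
      tr <- folds != f
      fit <- tryCatch(
        spec$fit(mat$x[tr, , drop = FALSE], y[tr], base_params[[b]],
                 seed = child_seed(seed, b * 10 + f)),
        error = function(e) stop("base '", spec$name, "' failed in fold ", f,
                                 ": ", conditionMessage(e)))
      oof[!tr, b] <- spec$predict_prob(fit, mat$x[!tr, , drop = FALSE])
      oof_rows[!tr] <- paste0("fold", f)
    }
  }
  beta <- ridge_logistic(oof, y, lambda)
  final_bases <- lapply(seq_along(base_specs), function(b) {
    base_specs[[b]]$fit(mat$x, y, base_params[[b]],
                        seed = child_seed(seed, 9000 + b))
  })
  stack_scores <- stack_prob(beta, oof)
  structure(list(base_specs = base_specs, base_params = base_params,
                 base_models = final_bases, beta = beta,
                 oof_design = data.frame(row_id = mat$row_ids,
                                         fold = oof_rows,
                                         stringsAsFactors = FALSE),
                 oof = oof, threshold = tune_threshold(y, stack_scores),
                 columns = colnames(mat$x), seed = seed),
            class = "nanotox_stack")
}

stack_prob <- function(beta, base_probs) {
  eta <- drop(cbind(1, as.matrix(base_probs)) %*% beta)
  1 / (1 + exp(-eta))
}

#' Predict with a stacking ensemble
#'
#' Scores rows with every final base model and passes the base probabilities
#' through the logistic meta-learner. Output is always in \[0, 1\].
#'
#' @param object A `nanotox_stack`.
#' @param newdata A `nanotox_matrix` or numeric matrix encoded with the
#'   training schema.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.nanotox_stack <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "nanotox_matrix")) newdata$x else as.matrix(newdata)
  if (!is.null(colnames(x)) && all(object$columns %in% colnames(x))) {
    x <- x[, object$columns, drop = FALSE]
  } else if (ncol(x) != length(object$columns)) {
    stop("newdata columns do not match the training schema")
  }
  base_probs <- vapply(seq_along(object$base_models), function(b) {
    object$base_specs[[b]]$predict_prob(object$base_models[[b]], x)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) base_probs <- matrix(base_probs, nrow = 1)
  p <- stack_prob(object$beta, base_probs)
  if (type == "prob") p else as.integer(p >= object$threshold)
}

#' @export
print.nanotox_stack <- function(x, ...) {
  cat("Stacking ensemble of", length(x$base_models), "base model(s):",
      paste(vapply(x$base_specs, `[[`, character(1), "name"), collapse = ", "),
      "\n")
  cat("  meta coefficients:",
      paste(names(x$beta), format(x$beta, digits = 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.nanotox_stack <- function(object, ...) object$beta
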