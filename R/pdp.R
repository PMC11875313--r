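#' Partial dependence of predicted toxicity on a continuous feature
#'
#' At each grid value (original units), the feature's encoded column is
#' overridden to `log10(value)` in every row and the model probabilities are
#' averaged, giving the marginal effect of the feature with all other
#' features held at their observed values.
#'
#' @param model A fitted model accepted by [attribute()]'s scorer.
#' @param mat A `nanotox_matrix`.
#' @param feature Continuous feature name (e.g. `"conc_ug_per_ml"`).
#' @param grid Numeric vector of feature values in original units; defaults
#'   to 25 points log-spaced over the observed range.
#' @return Object of class `nanotox_pdp`: `feature`, `grid`,
#'   `mean_prediction`.
#' @export
pdp <- function(model, mat, feature, grid = NULL) {
  if (!feature %in% mat$schema$continuous)
    stop("'", feature, "' is not a continuous feature")
  if (is.null(grid)) {
    r <- range(mat$x[, feature])             # stored on log10 scale
    grid <- 10^seq(r[1], r[2], length.out = 25)
  }
  if (length(grid) == 0) stop("empty grid")
  score <- score_function(model)
  mp <- vapply(grid, function(g) {
    x <- mat$x
    x[, feature] <- log10(g)
    mean(score(x))
  }, numeric(1))
  structure(list(feature = feature, grid = grid, mean_prediction = mp),
            class = "nanotox_pdp")
}

#' @export
print.nanotox_pdp <- function(x, ...) {
  cat("Partial dependence of toxicity probability on ", x$feature, ": ",
      length(x$grid), " grid points, range ",
      paste(format(range(x$mean_prediction), digits = 3), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.nanotox_pdp <- function(x, log = "x", ...) {
  plot(x$grid, x$mean_prediction, type = "b", log = log, xlab = x$feature,
       ylab = "mean predicted toxicity probability", ...)
  invisible(x)
}

#' Fit a four-parameter logistic to a partial dependence curve
#'
#' Fits `y = floor + (ceiling - floor) / (1 + exp(-slope * (x - inflection)))`
#' by least squares, with `x` the log10 of the grid when `log10_x = TRUE`
#' (the natural scale for concentration) or the raw grid otherwise (used for
#' exposure time). 95% confidence intervals come from the fit covariance.
#'
#' @param curve A `nanotox_pdp` (or list with `grid` and `mean_prediction`).
#' @param log10_x Fit against log10-transformed grid values.
#' @return Object of class `nanotox_fit` with `params`, `se`, `ci`,
#'   `fitted`, `r_squared`, `model = "sigmoid"`.
#' @export
fit_sigmoid <- function(curve, log10_x = TRUE) {
  y <- curve$mean_prediction
  xg <- if (log10_x) log10(curve$grid) else curve$grid
  if (length(y) < 5) stop("need at least 5 grid points for a 4PL fit")
  lo0 <- min(y); hi0 <- max(y)
  if (hi0 - lo0 < 1e-10) {
    # flat curve: the 4PL is unidentifiable; report a zero-slope fit whose
    # slope interval covers 0 rather than failing
    est <- c(floor = mean(y), ceiling = mean(y),
             inflection = mean(xg), slope = 0)
    se <- c(floor = 0, ceiling = 0, inflection = NA_real_, slope = Inf)
    ci <- cbind(lower = est - c(0, 0, Inf, Inf), upper = est + c(0, 0, Inf, Inf))
    rownames(ci) <- names(est)
    return(structure(list(model = "sigmoid", params = est, se = se, ci = ci,
                          fitted = rep(mean(y), length(y)), x = xg,
                          r_squared = 1, log10_x = log10_x),
                     class = "nanotox_fit"))
  }
  mid <- (lo0 + hi0) / 2
  infl0 <- xg[which.min(abs(y - mid))]
  slope0 <- if (cor(xg, y) >= 0) 4 / max(sd(xg), 1e-6) else -4 / max(sd(xg), 1e-6)
  df <- data.frame(x = xg, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ floor + (ceiling - floor) / (1 + exp(-slope * (x - inflection))),
      data = df,
      start = list(floor = lo0, ceiling = hi0, inflection = infl0,
                   slope = slope0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("sigmoid fit did not converge: ", conditionMessage(e),
           " (starting values: floor=", signif(lo0, 3), ", ceiling=",
           signif(hi0, 3), ", inflection=", signif(infl0, 3), ", slope=",
           signif(slope0, 3), ")")
    })
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(est)
  tq <- qt(0.975, max(length(y) - 4, 1))
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  fitted_y <- predict(fit)
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(model = "sigmoid", params = est, se = se, ci = ci,
                 fitted = fitted_y, x = xg,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 log10_x = log10_x),
            class = "nanotox_fit")
}

#' Fit a power-law (log-linear) trend to a partial dependence curve
#'
#' A power-law decay of toxicity probability with particle size is linear
#' against log10(size); the fit is ordinary least squares of the mean
#' prediction on log10 of the grid.
#'
#' @param curve A `nanotox_pdp` with strictly positive grid values.
#' @return Object of class `nanotox_fit` with `params` (`intercept`,
#'   `slope`), `ci`, `r_squared`, `model = "powerlaw"`.
#' @export
fit_powerlaw <- function(curve) {
  if (any(curve$grid <= 0)) stop("power-law fit requires positive grid values")
  xg <- log10(curve$grid)
  y <- curve$mean_prediction
  fit <- lm(y ~ xg)
  est <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  ci <- suppressWarnings(confint(fit))
  rownames(ci) <- c("intercept", "slope")
  ss_tot <- sum((y - mean(y))^2)
  # suppressed: lm warns on an exactly collinear (perfect) fit
  r2 <- if (ss_tot > 0) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(model = "powerlaw", params = est,
                 se = c(intercept = NA, slope = NA), ci = ci,
                 fitted = fitted(fit), x = xg, r_squared = r2),
            class = "nanotox_fit")
}

#' @export
print.nanotox_fit <- function(x, ...) {
  cat(x$model, "fit (R^2 =", format(x$r_squared, digits = 4), ")\n")
  for (p in names(x$params))
    cat(sprintf("  %-11s %10.4f  [%.4f, %.4f]\n", p, x$params[p],
                x$ci[p, 1], x$ci[p, 2]))
  invisible(x)
}

#' @export
coef.nanotox_fit <- function(object, ...) object$params

#' SHAP-guided iterative feature reduction
#'
#' Retrains the classifier on nested prefixes of the importance ranking
#' (most important feature first) and records PR-AUC, ROC-AUC, recall and
#' precision at each subset size from pooled out-of-fold cross-validation
#' scores. The plateau is the smallest prefix size after which the next
#' `patience` additions each improve PR-AUC by no more than `epsilon`.
#'
#' @param ranking Character vector of features, most important first (e.g.
#'   from [group_and_rank()]).
#' @param mat The full `nanotox_matrix`.
#' @param spec A [classifier_spec()].
#' @param params Hyperparameters used for every refit.
#' @param epsilon PR-AUC gain below which an addition counts as
#'   non-improving (default 0.005).
#' @param patience Consecutive non-improving additions defining the plateau
#'   (default 2).
#' @param k_eval Folds for the evaluation CV.
#' @param seed Integer seed.
#' @return Object of class `nanotox_reduction`: `trace` data frame,
#'   `plateau_size`, `ranking`.
#' @export
iterative_reduction <- function(ranking, mat, spec, params = list(),
                                epsilon = 0.005, patience = 2, k_eval = 5,
                                seed = 3) {
  missing_f <- setdiff(ranking, c(mat$schema$continuous, mat$schema$categorical))
  if (length(missing_f)) stop("ranking names unknown feature(s): ",
                              paste(missing_f, collapse = ", "))
  y <- mat$y
  folds <- stratified_folds(y, k_eval, seed)
  rows <- lapply(seq_along(ranking), function(s) {
    sub <- mat_select_features(mat, ranking[seq_len(s)])
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(k_eval)) {
      tr <- folds != f
      fit <- tryCatch(
        spec$fit(sub$x[tr, , drop = FALSE], y[tr], params,
                 seed = child_seed(seed, s * 50 + f)),
        error = function(e) stop("refit failed for feature subset {",
                                 paste(ranking[seq_len(s)], collapse = ", "),
                                 "}: ", conditionMessage(e)))
      oof[!tr] <- spec$predict_prob(fit, sub$x[!tr, , drop = FALSE])
    }
    rep_ <- metric_report(y, oof)
    data.frame(size = s, feature_added = ranking[s], pr_auc = rep_$pr_auc,
               roc_auc = rep_$roc_auc, recall = rep_$sensitivity,
               precision = rep_$precision)
  })
  trace <- do.call(rbind, rows)
  gains <- diff(trace$pr_auc)                 # gain of addition s+1 over s
  S <- length(ranking)
  plateau <- S
  for (s in seq_len(S)) {
    nxt <- seq(s, min(s + patience - 1, S - 1))
    if (s >= S || all(gains[nxt] <= epsilon)) { plateau <- s; break }
  }
  structure(list(trace = trace, plateau_size = plateau, ranking = ranking,
                 epsilon = epsilon, patience = patience),
            class = "nanotox_reduction")
}

#' @export
print.nanotox_reduction <- function(x, ...) {
  cat("Iterative feature reduction (plateau at", x$plateau_size,
      "features)\n")
  print(x$trace, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.nanotox_reduction <- function(x, ...) {
  plot(x$trace$size, x$trace$pr_auc, type = "b", xlab = "features included",
       ylab = "PR-AUC", ...)
  abline(v = x$plateau_size, lty = 2)
  invisible(x)
}
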