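small_data <- function(n = 300, seed = 3) {
  ds <- gen_invitro(synth_config(n = n, seed = seed))
  encode(harmonize(ds$records))
}

test_that("stratified folds balance sizes and class counts", {
  labels <- c(rep(1, 37), rep(0, 63))
  folds <- stratified_folds(labels, 10, seed = 1)
  sizes <- table(folds)
  expect_true(all(sizes == 10))
  pos <- tapply(labels, folds, sum)
  expect_true(all(pos %in% c(3, 4)))
  expect_identical(folds, stratified_folds(labels, 10, seed = 1))
  expect_false(identical(folds, stratified_folds(labels, 10, seed = 2)))
  expect_error(stratified_folds(labels, 1), "at least 2")
  expect_error(stratified_folds(c(1, 0, 0, 0), 3), "at least k")
})

test_that("inner search maximizes mean inner-fold PR-AUC with stable ties", {
  mat <- small_data(240)
  sp <- spec_random_forest()
  # singleton grid returns that point untouched
  res <- inner_search(mat$x, mat$y, sp, list(min_node_size = 5), k_inner = 3,
                      seed = 3)
  expect_equal(res$best_params$min_node_size, 5)
  # two identical points tie toward the first in grid order
  res2 <- inner_search(mat$x, mat$y, sp,
                       list(min_node_size = c(5, 5)), k_inner = 3, seed = 3)
  expect_equal(res2$results$mean_pr_auc[1], res2$results$mean_pr_auc[2])
  expect_equal(res2$best_params$min_node_size, 5)
  expect_equal(which.max(res2$results$mean_pr_auc), 1L)
})

test_that("failing grid points are skipped; an all-failure grid errors", {
  mat <- small_data(240)
  flaky <- classifier_spec(
    name = "flaky",
    fit = function(x, y, params, seed) {
      if (isTRUE(params$explode)) stop("boom")
      list(mean = mean(y))
    },
    predict_prob = function(model, x) rep(model$mean, nrow(x)))
  expect_warning(
    res <- inner_search(mat$x, mat$y, flaky,
                        list(explode = c(TRUE, FALSE)), k_inner = 3, seed = 3),
    "failed")
  expect_false(isTRUE(res$best_params$explode))
  expect_error(
    suppressWarnings(inner_search(mat$x, mat$y, flaky, list(explode = TRUE),
                                  k_inner = 3, seed = 3)),
    "every grid point failed")
})

test_that("nested CV partitions cleanly and never leaks rows", {
  mat <- small_data(300)
  sp <- spec_random_forest()
  ncv <- nested_cv(mat, sp, grid = list(min_node_size = c(1, 5)),
                   k_outer = 5, k_inner = 3, seed = 3)
  expect_length(ncv$fold_results, 5)
  all_test <- unlist(lapply(ncv$fold_results, `[[`, "test_row_ids"))
  expect_setequal(all_test, mat$row_ids)        # outer folds partition rows
  for (fr in ncv$fold_results) {
    expect_length(intersect(fr$test_row_ids, fr$train_row_ids), 0)
    expect_length(fr$scores, length(fr$test_row_ids))
  }
  expect_equal(vapply(ncv$fold_results, function(f) length(f$scores),
                      integer(1)), rep(60L, 5))
})

test_that("consolidated grids deduplicate per-fold winners order-preservingly", {
  expect_equal(consolidate_grid(list(list(depth = 6), list(depth = 6))),
               list(depth = 6))
  got <- consolidate_grid(list(list(lr = 0.1), list(lr = 0.1),
                               list(lr = 0.05)))
  expect_equal(got, list(lr = c(0.1, 0.05)))
  # refined product never exceeds the original product
  per_fold <- list(list(a = 1, b = "x"), list(a = 2, b = "x"),
                   list(a = 1, b = "x"))
  refined <- consolidate_grid(per_fold)
  expect_lte(prod(lengths(refined)), 3 * 2)
  expect_equal(refined$a, c(1, 2)); expect_equal(refined$b, "x")
})

test_that("the end-to-end trainer is deterministic and beats the baseline", {
  mat <- small_data(400)
  sp <- spec_gbt("depthwise")
  grid <- list(max_depth = 3, eta = c(0.1, 0.3), max_rounds = 150,
               patience = 15)
  fit1 <- nanotox_train(mat, sp, grid, k_outer = 3, k_inner = 3, seed = 3)
  fit2 <- nanotox_train(mat, sp, grid, k_outer = 3, k_inner = 3, seed = 3)
  expect_equal(fit1$params, fit2$params)
  expect_equal(fit1$threshold, fit2$threshold)
  p1 <- predict(fit1, mat); p2 <- predict(fit2, mat)
  expect_lt(max(abs(p1 - p2)), 1e-6)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # planted signal: outer PR-AUC clears the prevalence baseline
  expect_gt(mean(fit1$ncv$outer_pr_auc), mean(mat$y))
  # class predictions use the tuned threshold
  expect_equal(predict(fit1, mat, type = "class"),
               as.integer(p1 >= fit1$threshold))
})

test_that("early stopping halts before the round cap on separable data", {
  fix <- withr::with_seed(5, {
    x <- matrix(rnorm(400 * 4), 400, 4)
    y <- as.integer(x[, 1] > 0)        # noiseless, separable on one feature
    list(x = x, y = y)
  })
  sp <- spec_gbt("depthwise")
  res <- early_stopping_fit(sp, fix$x, fix$y, params = list(eta = 0.3),
                            seed = 3)
  expect_lt(res$best_round, 5000)
  res2 <- early_stopping_fit(sp, fix$x, fix$y, params = list(eta = 0.3),
                             seed = 3)
  expect_equal(res$best_round, res2$best_round)
  # patience beyond the cap: runs to max_rounds without error
  res3 <- early_stopping_fit(sp, fix$x, fix$y, params = list(eta = 0.3),
                             max_rounds = 8, patience = 50, seed = 3)
  expect_lte(res3$best_round, 8)
  # a 10% holdout needs at least 10 rows
  expect_error(early_stopping_fit(sp, fix$x[1:40, ], fix$y[1:40], seed = 3),
               "holdout")
  expect_error(early_stopping_fit(spec_random_forest(), fix$x, fix$y),
               "does not support early stopping")
})

test_that("a planted Bayes-optimal grid point wins the inner search", {
  # toy where only the first feature matters and a depth-1 tree is optimal;
  # the memorizing depth is never better on held-out folds
  fix <- withr::with_seed(9, {
    x <- matrix(rnorm(300 * 3), 300, 3)
    y <- as.integer(x[, 1] + rnorm(300, sd = 0.2) > 0)
    list(x = x, y = y)
  })
  sp <- spec_gbt("depthwise")
  res <- inner_search(fix$x, fix$y, sp,
                      list(max_depth = c(1, 6), eta = 0.3, max_rounds = 60,
                           patience = 10),
                      k_inner = 3, seed = 3)
  expect_equal(res$best_params$max_depth, 1)
})
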