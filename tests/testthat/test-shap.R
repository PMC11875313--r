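toy_matrix <- function(x, labels = NULL) {
  # wrap a plain matrix as a nanotox_matrix with an all-continuous schema
  # (features already encoded; one column per feature)
  rec <- as.data.frame(x)
  schema <- structure(list(continuous = colnames(x), categorical = character(),
                           category_levels = list(),
                           dropped_level = character()),
                      class = "nanotox_schema")
  structure(list(x = x, y = labels, schema = schema,
                 row_ids = as.character(seq_len(nrow(x)))),
            class = "nanotox_matrix")
}

test_that("a depth-1 stump attributes the full deviation to its split feature", {
  cols <- c("f1", "f2", "f3")
  tree <- make_tree(feature = c(1, NA, NA), split = c(0.5, NA, NA),
                    left = c(2, NA, NA), right = c(3, NA, NA),
                    value = c(NA, 0.2, 0.8))
  fo <- nanotox_forest(list(tree), cols)
  x <- matrix(c(1, 0, 0), 1, 3, dimnames = list(NULL, cols))   # goes right
  bg <- matrix(c(0, 1, 1), 1, 3, dimnames = list(NULL, cols))  # goes left
  sh <- shap_tree(fo, x, bg)
  expect_equal(unname(sh$values[1, ]), c(0.6, 0, 0))
  expect_equal(sh$base_value, 0.2)
})

test_that("a constant model yields zero attributions and its value as base", {
  tree <- make_tree(feature = NA, split = NA, left = NA, right = NA,
                    value = 0.35)
  fo <- nanotox_forest(list(tree), c("a", "b"))
  x <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  sh <- shap_tree(fo, x, x)
  expect_equal(unname(sh$values), matrix(0, 3, 2))
  expect_equal(sh$base_value, 0.35)
})

test_that("tree-path attributions equal brute-force Shapley on a 3-feature toy", {
  cols <- c("f1", "f2", "f3")
  # two interacting trees with repeated features along paths
  t1 <- make_tree(feature = c(1, 2, NA, NA, NA), split = c(0, 1, NA, NA, NA),
                  left = c(2, 4, NA, NA, NA), right = c(3, 5, NA, NA, NA),
                  value = c(NA, NA, 0.9, 0.1, 0.5))
  t2 <- make_tree(feature = c(3, 1, NA, NA, NA), split = c(0.5, -1, NA, NA, NA),
                  left = c(2, 4, NA, NA, NA), right = c(3, 5, NA, NA, NA),
                  value = c(NA, NA, 0.3, 0.7, 0.2))
  fo <- nanotox_forest(list(t1, t2), cols)
  fix <- withr::with_seed(4, list(x = matrix(rnorm(9), 3, 3,
                                             dimnames = list(NULL, cols)),
                                  bg = matrix(rnorm(15), 5, 3,
                                              dimnames = list(NULL, cols))))
  sh <- shap_tree(fo, fix$x, fix$bg)
  groups <- list(f1 = 1L, f2 = 2L, f3 = 3L)
  for (i in 1:3) {
    brute <- brute_shapley(function(z) forest_predict(fo, z),
                           fix$x[i, ], fix$bg, groups)
    expect_equal(unname(sh$values[i, ]), brute, tolerance = 1e-9)
  }
  # local accuracy
  preds <- forest_predict(fo, fix$x)
  expect_equal(sh$base_value + rowSums(sh$values), preds, tolerance = 1e-9)
})

test_that("subset-enumeration attributions match the brute-force definition", {
  fix <- withr::with_seed(8, list(x = matrix(runif(8), 2, 4),
                                  bg = matrix(runif(12), 3, 4)))
  score <- function(z) plogis(z[, 1] - 2 * z[, 2] + z[, 3] * z[, 4])
  groups <- list(g1 = 1L, g2 = 2L, g34 = c(3L, 4L))
  sh <- shap_exact(score, fix$x, fix$bg, groups)
  for (i in 1:2) {
    brute <- brute_shapley(score, fix$x[i, ], fix$bg, groups)
    expect_equal(unname(sh$values[i, ]), brute, tolerance = 1e-9)
  }
  expect_equal(sh$base_value + rowSums(sh$values), score(fix$x),
               tolerance = 1e-9)
})

test_that("fitted forest attributions are exact and locally accurate", {
  fix <- withr::with_seed(21, {
    x <- matrix(rnorm(120 * 5), 120, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- as.integer(x[, 1] + 0.5 * x[, 2] - x[, 3] + rnorm(120, sd = .3) > 0)
    list(x = x, y = y)
  })
  sp <- spec_random_forest()
  rf <- sp$fit(fix$x, fix$y, list(num_trees = 15), seed = 3)
  fo <- forest_from_ranger(rf, colnames(fix$x))
  xe <- fix$x[1:4, , drop = FALSE]
  bg <- fix$x[5:12, , drop = FALSE]
  sh <- shap_tree(fo, xe, bg)
  groups <- as.list(setNames(1:5, colnames(fix$x)))
  brute <- brute_shapley(function(z) forest_predict(fo, z), xe[2, ], bg,
                         groups)
  expect_equal(unname(sh$values[2, ]), brute, tolerance = 1e-9)
  expect_equal(sh$base_value + rowSums(sh$values), forest_predict(fo, xe),
               tolerance = 1e-6)
})

test_that("grouping conserves per-sample totals and ranks planted effects", {
  ds <- gen_invitro(synth_config(n = 500, seed = 3))
  mat <- encode(harmonize(ds$records))
  sp <- spec_random_forest()
  model <- structure(list(spec = sp,
                          model = sp$fit(mat$x, mat$y, list(num_trees = 40),
                                         seed = 3),
                          columns = colnames(mat$x), schema = mat$schema,
                          threshold = 0.5),
                     class = "nanotox_model")
  att <- attribute(model, nanotox:::mat_rows(mat, 1:40), n_background = 25,
                   seed = 3)
  expect_equal(att$level, "column")
  grouped <- group_and_rank(att)
  # grouping is a signed sum: per-sample totals conserved exactly
  expect_equal(rowSums(grouped$values), rowSums(att$values),
               tolerance = 1e-12)
  # single-column (continuous) features group to themselves
  expect_equal(grouped$values[, "size_nm"], att$values[, "size_nm"])
  # local accuracy survives grouping
  preds <- predict(model, mat$x[1:40, , drop = FALSE])
  expect_equal(att$base_value + rowSums(grouped$values), preds,
               tolerance = 1e-6)
  expect_error(group_and_rank(structure(list(values = matrix(0, 1, 1,
    dimnames = list(NULL, "ghost")), level = "column", schema = mat$schema),
    class = "attribution_table")), "unmapped")
})

test_that("rank consensus behaves as a correlation", {
  a <- c(f1 = 3, f2 = 2, f3 = 1)
  b <- c(f1 = 30, f2 = 20, f3 = 10)     # same ranking, different scale
  r <- consensus(list(m1 = a, m2 = b))
  expect_equal(unname(r["m1", "m2"]), 1)
  expect_equal(diag(r), c(m1 = 1, m2 = 1))
  rev_ <- c(f1 = 1, f2 = 2, f3 = 3)
  expect_equal(unname(consensus(list(a, rev_))[1, 2]), -1)
  expect_true(isSymmetric(consensus(list(a, b, rev_))))
  expect_error(consensus(list(a, c(f1 = 1, f9 = 2, f3 = 3))), "mismatched")
  expect_error(consensus(list(a)), "at least 2")
  # independent random rankings decorrelate on average
  rs <- vapply(1:300, function(i) withr::with_seed(i, {
    consensus(list(setNames(sample(10), paste0("f", 1:10)),
                   setNames(sample(10), paste0("f", 1:10))))[1, 2]
  }), numeric(1))
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("categorical summaries use medians over level-restricted samples", {
  ds <- gen_invitro(synth_config(n = 300, seed = 7))
  mat <- encode(harmonize(ds$records))
  vals <- withr::with_seed(1, matrix(rnorm(nrow(mat$x) * 2), ncol = 2,
    dimnames = list(NULL, c("composition", "size_nm"))))
  grouped <- structure(list(values = vals, importance = NULL, ranking = NULL),
                       class = "grouped_attribution")
  out <- categorical_summary(grouped, mat, "composition")
  lev <- decode(mat)$composition
  for (k in seq_len(nrow(out))) {
    expect_equal(out$median_attribution[k],
                 median(vals[lev == out$level[k], "composition"]))
  }
  one <- out[out$n == 1, ]
  if (nrow(one) > 0) {
    expect_equal(one$median_attribution[1],
                 vals[lev == one$level[1], "composition"])
  }
  expect_error(categorical_summary(grouped, mat, "size_nm"),
               "not categorical")
})
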