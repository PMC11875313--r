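test_that("zeta potentials map to the four surface-charge classes", {
  expect_equal(categorize_zeta(c(15, 10, -10, -25, 10.001, -10.001, NA)),
               c("positive", "neutral", "neutral", "negative", "positive",
                 "negative", "not_determined"))
  expect_error(categorize_zeta(c("high", 5)), "non-numeric")
})

test_that("viability binarizes at the 70% threshold, toxic below", {
  expect_equal(binarize_viability(c(70, 69.9, 100, 0)), c(0L, 1L, 0L, 1L))
  expect_error(binarize_viability(-1), "negative")
  expect_error(binarize_viability(c(50, NA)), "missing")
})

test_that("missing coating and shape impute to Unmodified / Sphere", {
  rec <- data.frame(coating = c(NA, "PEG", ""), shape = c("Rod", NA, NA),
                    stringsAsFactors = FALSE)
  out <- impute_missing_categoricals(rec)
  expect_equal(out$coating, c("Unmodified", "PEG", "Unmodified"))
  expect_equal(out$shape, c("Rod", "Sphere", "Sphere"))
})

test_that("IQR outlier flags match hand-computed type-7 fences", {
  # quartiles of 1:4,100 by linear interpolation: Q1=2, Q3=4 -> fence 7
  expect_equal(flag_outliers_iqr(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(flag_outliers_iqr(rep(5, 5)), rep(FALSE, 5))
  expect_equal(flag_outliers_iqr(1:5), rep(FALSE, 5))
  expect_error(flag_outliers_iqr(c(1, 2, NA, NA)), "at least 4")
})

make_raw <- function(n = 40, seed = 11) {
  withr::with_seed(seed, data.frame(
    size_nm = 10^runif(n, 0.5, 2.5),
    conc_ug_per_ml = 10^runif(n, -1, 4),
    time_h = 10^runif(n, -0.5, 2),
    zeta_mv = sample(c(-30, -5, 20, NA), n, TRUE),
    viability_pct = runif(n, 20, 110),
    composition = sample(c("SiO2", "Ag", "ZnO"), n, TRUE),
    coating = sample(c("Unmodified", "PEG", NA), n, TRUE),
    shape = sample(c("Sphere", "Rod", NA), n, TRUE),
    species = "human", organ = sample(c("lungs", "skin"), n, TRUE),
    cell_class = sample(c("cell_line", "primary"), n, TRUE),
    stringsAsFactors = FALSE))
}

test_that("harmonize enforces the label rule and rejects log-undefined rows", {
  raw <- make_raw()
  raw$conc_ug_per_ml[3] <- 0
  raw$size_nm[7] <- -2
  cur <- harmonize(raw)
  expect_s3_class(cur, "nanotox_records")
  expect_false(any(c("3", "7") %in% cur$row_id))
  expect_true(any(grepl("non-positive", attr(cur, "log"))))
  # every surviving record obeys the viability rule
  expect_equal(cur$label, binarize_viability(cur$viability_pct))
  # zeta class is consistent with the measured value
  expect_equal(cur$zeta_class, categorize_zeta(cur$zeta_mv))
})

test_that("outlier allowlist retains flagged records", {
  raw <- make_raw()
  raw$size_nm[5] <- 1e9   # wild outlier on log scale
  dropped <- harmonize(raw)
  expect_false("5" %in% dropped$row_id)
  kept <- harmonize(raw, keep_ids = "5")
  expect_true("5" %in% kept$row_id)
})

test_that("encoding log-transforms, drops the least frequent level, and inverts", {
  rec <- data.frame(
    size_nm = c(100, 10, 1000, 10, 100),
    conc_ug_per_ml = c(1, 10, 100, 1000, 1),
    time_h = c(24, 24, 48, 48, 24),
    composition = c("A", "A", "A", "B", "B"),   # C absent here
    coating = c("A", "A", "B", "B", "C"),       # counts A:2 B:2 C:1 -> drop C
    label = c(0, 1, 0, 1, 0), stringsAsFactors = FALSE)
  schema <- build_schema(rec, categorical = c("composition", "coating"))
  expect_equal(unname(schema$dropped_level["coating"]), "C")
  # tie A:3 vs B:2? composition counts A:3 B:2 -> drop B
  expect_equal(unname(schema$dropped_level["composition"]), "B")
  mat <- encode(rec, schema)
  expect_equal(unname(mat$x[1, "size_nm"]), 2)  # log10(100)
  expect_equal(colnames(mat$x),
               c("size_nm", "conc_ug_per_ml", "time_h", "composition=A",
                 "coating=A", "coating=B"))
  # record carrying the dropped level encodes all zeros in that block
  expect_equal(unname(mat$x[5, c("coating=A", "coating=B")]), c(0, 0))
  # one-hot rows sum to at most 1 per feature
  expect_true(all(rowSums(mat$x[, c("coating=A", "coating=B")]) <= 1))
  # round trip through decode
  dec <- decode(mat)
  expect_equal(dec$composition, rec$composition)
  expect_equal(dec$coating, rec$coating)
  expect_equal(dec$size_nm, log10(rec$size_nm))
  # idempotence under a frozen schema
  expect_identical(mat$x, encode(rec, schema)$x)
})

test_that("least-frequent ties break to the lexicographically smallest level", {
  rec <- data.frame(size_nm = c(1, 1, 1, 1), conc_ug_per_ml = 1, time_h = 1,
                    composition = c("B", "A", "B", "A"),
                    stringsAsFactors = FALSE)
  schema <- build_schema(rec, categorical = "composition")
  expect_equal(unname(schema$dropped_level["composition"]), "A")
})

test_that("unseen levels encode as zeros with a warning", {
  rec <- data.frame(size_nm = 10, conc_ug_per_ml = 1, time_h = 1,
                    composition = c("A", "A", "B"), stringsAsFactors = FALSE)
  schema <- build_schema(rec, categorical = "composition")
  new <- data.frame(size_nm = 10, conc_ug_per_ml = 1, time_h = 1,
                    composition = "Z", stringsAsFactors = FALSE)
  expect_warning(m2 <- encode(new, schema), "unseen")
  expect_equal(unname(m2$x[1, "composition=A"]), 0)
})

test_that("train/test split is disjoint, seeded, and stratified within 1%", {
  ds <- gen_invitro(synth_config(n = 1000, seed = 5))
  mat <- encode(harmonize(ds$records))
  parts <- split_dataset(mat, 0.2, seed = 42)
  expect_equal(nrow(parts$train$x) + nrow(parts$test$x), nrow(mat$x))
  expect_length(intersect(parts$train$row_ids, parts$test$row_ids), 0)
  expect_equal(nrow(parts$test$x), round(0.2 * nrow(mat$x)), tolerance = 2)
  prev <- mean(mat$y)
  expect_lt(abs(mean(parts$test$y) - prev), 0.01)
  expect_lt(abs(mean(parts$train$y) - prev), 0.01)
  # determinism
  parts2 <- split_dataset(mat, 0.2, seed = 42)
  expect_identical(parts$test_idx, parts2$test_idx)
  # unstratified flag still splits
  p3 <- split_dataset(mat, 0.2, seed = 42, stratify = FALSE)
  expect_equal(nrow(p3$test$x), round(0.2 * nrow(mat$x)))
  expect_error(split_dataset(mat, 1.2), "test_fraction")
})
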