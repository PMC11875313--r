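CONTINUOUS_FEATURES <- c("size_nm", "conc_ug_per_ml", "time_h")
CATEGORICAL_FEATURES <- c("composition", "coating", "shape", "zeta_class",
                          "species", "organ", "cell_class")

#' Build a feature schema from curated records
#'
#' Records, per categorical feature, the observed levels with their counts and
#' the level omitted from one-hot encoding. The omitted level is the least
#' frequent one (dummy-variable-trap convention); ties are broken toward the
#' lexicographically smallest level so the choice is deterministic.
#'
#' @param records Curated records (see [harmonize()]).
#' @param continuous,categorical Feature names to include; defaults cover the
#'   full descriptor set.
#' @return Object of class `nanotox_schema`.
#' @export
build_schema <- function(records,
                         continuous = intersect(CONTINUOUS_FEATURES, names(records)),
                         categorical = intersect(CATEGORICAL_FEATURES, names(records))) {
  levels_list <- list()
  dropped <- character()
  for (f in categorical) {
    tab <- table(as.character(records[[f]]))
    tab <- tab[order(names(tab))]            # deterministic level order
    levels_list[[f]] <- as.integer(tab)
    names(levels_list[[f]]) <- names(tab)
    min_count <- min(tab)
    dropped[f] <- sort(names(tab)[tab == min_count])[1]
  }
  structure(list(continuous = continuous, categorical = categorical,
                 category_levels = levels_list, dropped_level = dropped),
            class = "nanotox_schema")
}

#' Column names of the encoded design matrix for a schema
#' @param schema A `nanotox_schema`.
#' @return Character vector of encoded column names, continuous features first,
#'   then `feature=level` one-hot columns.
#' @export
schema_columns <- function(schema) {
  onehot <- unlist(lapply(schema$categorical, function(f) {
    keep <- setdiff(names(schema$category_levels[[f]]), schema$dropped_level[f])
    if (length(keep)) paste0(f, "=", keep) else character()
  }))
  c(schema$continuous, onehot)
}

#' Map encoded columns back to their source feature
#' @param schema A `nanotox_schema`.
#' @return Named character vector: for each encoded column, the original
#'   feature it belongs to.
#' @export
column_feature_map <- function(schema) {
  cols <- schema_columns(schema)
  feat <- ifelse(cols %in% schema$continuous, cols, sub("=.*$", "", cols))
  setNames(feat, cols)
}

#' Encode curated records into a numeric design matrix
#'
#' Continuous features are log10-transformed; categorical features are one-hot
#' encoded with the least frequent level dropped per feature. When applying a
#' frozen schema to new data, a level unseen at schema-build time encodes as
#' all zeros for that feature and a warning is emitted.
#'
#' @param records Curated records.
#' @param schema Optional frozen `nanotox_schema`; built from `records` if
#'   omitted.
#' @return Object of class `nanotox_matrix`: list with `x` (numeric matrix),
#'   `y` (integer labels, if `records$label` exists), `schema`, `row_ids`.
#' @export
encode <- function(records, schema = NULL) {
  if (is.null(schema)) schema <- build_schema(records)
  cols <- schema_columns(schema)
  n <- nrow(records)
  x <- matrix(0, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
  for (f in schema$continuous) {
    v <- as.numeric(records[[f]])
    if (any(v <= 0, na.rm = TRUE)) stop("non-positive value in '", f, "' cannot be log-transformed")
    x[, f] <- log10(v)
  }
  for (f in schema$categorical) {
    lev <- as.character(records[[f]])
    known <- names(schema$category_levels[[f]])
    unseen <- setdiff(unique(lev), known)
    if (length(unseen))
      warning("feature '", f, "': unseen level(s) ", paste(unseen, collapse = ", "),
              " encoded as all zeros")
    for (l in setdiff(known, schema$dropped_level[f])) {
      x[, paste0(f, "=", l)] <- as.numeric(lev == l)
    }
  }
  row_ids <- if ("row_id" %in% names(records)) as.character(records$row_id)
             else as.character(seq_len(n))
  y <- if ("label" %in% names(records)) as.integer(records$label) else NULL
  structure(list(x = x, y = y, schema = schema, row_ids = row_ids),
            class = "nanotox_matrix")
}

#' Decode an encoded matrix back to feature values
#'
#' Inverts [encode()]: continuous columns return their log10 values (as
#' stored), one-hot blocks return the categorical level (the dropped level for
#' an all-zero block).
#'
#' @param mat A `nanotox_matrix`.
#' @return Data frame with one column per original feature.
#' @export
decode <- function(mat) {
  schema <- mat$schema
  out <- as.data.frame(mat$x[, schema$continuous, drop = FALSE])
  for (f in schema$categorical) {
    keep <- setdiff(names(schema$category_levels[[f]]), schema$dropped_level[f])
    if (length(keep)) {
      block <- mat$x[, paste0(f, "=", keep), drop = FALSE]
      idx <- apply(block, 1, function(r) {
        j <- which(r == 1)
        if (length(j) == 1) keep[j] else schema$dropped_level[[f]]
      })
      out[[f]] <- idx
    } else {
      out[[f]] <- rep(schema$dropped_level[[f]], nrow(mat$x))
    }
  }
  out
}

#' @export
print.nanotox_matrix <- function(x, ...) {
  cat("Encoded design matrix: ", nrow(x$x), " x ", ncol(x$x), sep = "")
  if (!is.null(x$y)) cat(" (", round(100 * mean(x$y), 1), "% toxic)", sep = "")
  cat("\nFeatures: ", length(x$schema$continuous), " continuous + ",
      length(x$schema$categorical), " categorical\n", sep = "")
  invisible(x)
}

# Internal: subset rows of a nanotox_matrix.
mat_rows <- function(mat, idx) {
  structure(list(x = mat$x[idx, , drop = FALSE],
                 y = if (!is.null(mat$y)) mat$y[idx],
                 schema = mat$schema, row_ids = mat$row_ids[idx]),
            class = "nanotox_matrix")
}

# Internal: keep only encoded columns belonging to the given original features.
mat_select_features <- function(mat, features) {
  fmap <- column_feature_map(mat$schema)
  keep <- names(fmap)[fmap %in% features]
  out <- mat
  out$x <- mat$x[, keep, drop = FALSE]
  out
}

#' Split an encoded dataset into training and test partitions
#'
#' Shuffles and splits row indices, stratified by label so the class
#' prevalence of each partition stays within 1% of the whole. Stratification
#' can be disabled to get a plain shuffled split.
#'
#' @param mat A `nanotox_matrix` with labels.
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @param stratify Stratify by label (default `TRUE`).
#' @return List with `train` and `test` (`nanotox_matrix` objects) and the row
#'   index vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(mat, test_fraction = 0.2, seed = 3, stratify = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0, 1)")
  y <- mat$y
  if (is.null(y)) stop("matrix has no labels")
  if (min(table(y)) < 10) stop("need at least 10 rows of each class")
  test_idx <- with_seed(seed, {
    if (stratify) {
      unlist(lapply(split(seq_along(y), y), function(idx) {
        idx <- sample(idx)
        idx[seq_len(round(length(idx) * test_fraction))]
      }), use.names = FALSE)
    } else {
      idx <- sample(seq_along(y))
      idx[seq_len(round(length(idx) * test_fraction))]
    }
  })
  train_idx <- setdiff(seq_along(y), test_idx)
  list(train = mat_rows(mat, train_idx), test = mat_rows(mat, test_idx),
       train_idx = sort(train_idx), test_idx = sort(test_idx))
}

#' Read a raw nanoparticle record CSV
#'
#' Column dictionary (units in headers): `size_nm`, `conc_ug_per_ml`,
#' `time_h`, `zeta_mv`, `viability_pct`, `composition`, `coating`, `shape`,
#' `species`, `organ`, `cell_class`, optional `row_id`.
#'
#' @param path CSV file path.
#' @return Data frame of raw records.
#' @export
read_nanotox_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
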