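# --- standardized tree-ensemble representation -------------------------------
#
# A `nanotox_forest` holds an ensemble whose prediction is the MEAN of
# per-tree leaf values (the form taken by probability forests, where each
# leaf stores a class fraction). Each tree is a data frame with 1-based node
# ids: feature (integer column index, NA at leaves), split (numeric), left,
# right (child ids), value (leaf value). Convention: descend LEFT when
# x[feature] <= split.

#' Build a tree-ensemble container
#'
#' @param trees List of node data frames (`feature`, `split`, `left`,
#'   `right`, `value`); see source for the convention.
#' @param columns Encoded column names the feature indices refer to.
#' @return Object of class `nanotox_forest`.
#' @export
nanotox_forest <- function(trees, columns) {
  structure(list(trees = trees, columns = columns), class = "nanotox_forest")
}

#' Convert a fitted ranger probability forest to a `nanotox_forest`
#'
#' Leaf values are the class-1 fractions, so the ensemble probability equals
#' the mean of per-tree leaf values and Shapley attributions computed on the
#' trees live directly in probability space.
#'
#' @param rf A `ranger` probability forest.
#' @param columns Column names of the design matrix the forest was fit on.
#' @return A `nanotox_forest`.
#' @export
forest_from_ranger <- function(rf, columns) {
  trees <- lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    data.frame(feature = ifelse(ti$terminal, NA_integer_, ti$splitvarID + 1L),
               split = ti$splitval,
               left = ti$leftChild + 1L, right = ti$rightChild + 1L,
               value = if ("pred.1" %in% names(ti)) ti$pred.1 else ti$prediction)
  })
  nanotox_forest(trees, columns)
}

#' Predict with a `nanotox_forest` (mean of per-tree leaf values)
#' @param forest A `nanotox_forest`.
#' @param x Numeric matrix.
#' @return Numeric vector of ensemble outputs.
#' @export
forest_predict <- function(forest, x) {
  x <- as.matrix(x)
  total <- numeric(nrow(x))
  for (tree in forest$trees) {
    node <- rep(1L, nrow(x))
    repeat {
      leaf <- is.na(tree$feature[node])
      if (all(leaf)) break
      j <- which(!leaf)
      f <- tree$feature[node[j]]
      goleft <- x[cbind(j, f)] <= tree$split[node[j]]
      node[j] <- ifelse(goleft, tree$left[node[j]], tree$right[node[j]])
    }
    total <- total + tree$value[node]
  }
  total / length(forest$trees)
}

# Internal: enumerate the leaves of one tree as per-feature intervals.
# Returns a list of leaves: list(features, lo, hi, value); a point x reaches
# the leaf iff lo < x[f] <= hi for every constrained feature f.
tree_leaves <- function(tree) {
  leaves <- list()
  walk <- function(node, lo, hi) {
    f <- tree$feature[node]
    if (is.na(f)) {
      j <- which(is.finite(lo) | is.finite(hi))
      leaves[[length(leaves) + 1L]] <<- list(features = j, lo = lo[j],
                                             hi = hi[j],
                                             value = tree$value[node])
      return(invisible())
    }
    s <- tree$split[node]
    hi2 <- hi; hi2[f] <- min(hi2[f], s)
    if (hi2[f] > lo[f]) walk(tree$left[node], lo, hi2)
    lo2 <- lo; lo2[f] <- max(lo2[f], s)
    if (hi[f] > lo2[f]) walk(tree$right[node], lo2, hi)
    invisible()
  }
  p <- suppressWarnings(max(tree$feature, na.rm = TRUE))
  if (!is.finite(p)) p <- 1L                   # single-leaf (constant) tree
  walk(1L, rep(-Inf, p), rep(Inf, p))
  leaves
}

#' Exact interventional Shapley attributions for a tree ensemble
#'
#' Computes, for every explained row, the exact Shapley value of each encoded
#' column for the game in which features absent from a coalition are drawn
#' from a background sample. The computation is polynomial: for each leaf and
#' each (row, background) pair, the leaf's path constraints partition its
#' features into those that must be present (satisfied by the row but not the
#' background) and those that must be absent, and the Shapley weight of such
#' a leaf has closed form. Attributions satisfy local accuracy exactly:
#' base value plus the attribution sum reproduces the model probability.
#'
#' @param forest A `nanotox_forest` (see [forest_from_ranger()]).
#' @param x Numeric matrix of rows to explain.
#' @param background Numeric matrix of background rows (the reference
#'   distribution for absent features).
#' @return List with `values` (rows x columns attribution matrix) and
#'   `base_value` (mean model output over the background).
#' @export
shap_tree <- function(forest, x, background) {
  x <- as.matrix(x); background <- as.matrix(background)
  n <- nrow(x); p <- ncol(x); nb <- nrow(background)
  phi <- matrix(0, n, p, dimnames = list(NULL, forest$columns))
  # Shapley weights for a leaf with k must-present and m must-absent features
  maxd <- 64
  lf <- lgamma(seq_len(maxd + 1))            # lf[i] = lgamma(i) = log((i-1)!)
  wx <- function(k, m) exp(lf[k] + lf[m + 1] - lf[k + m + 1])
  wb <- function(k, m) exp(lf[k + 1] + lf[m] - lf[k + m + 1])
  for (tree in forest$trees) {
    for (leaf in tree_leaves(tree)) {
      J <- leaf$features
      if (length(J) == 0) next                   # constant tree: base only
      val <- leaf$value
      A <- matrix(TRUE, n, length(J))
      B <- matrix(TRUE, nb, length(J))
      for (jj in seq_along(J)) {
        A[, jj] <- x[, J[jj]] > leaf$lo[jj] & x[, J[jj]] <= leaf$hi[jj]
        B[, jj] <- background[, J[jj]] > leaf$lo[jj] &
                   background[, J[jj]] <= leaf$hi[jj]
      }
      for (g in seq_len(nb)) {
        bv <- B[g, ]
        M1 <- A & rep(!bv, each = n)             # feature must be present
        M2 <- (!A) & rep(bv, each = n)           # feature must be absent
        dead <- rowSums((!A) & rep(!bv, each = n)) > 0
        k <- rowSums(M1); m <- rowSums(M2)
        act <- !dead & (k + m) > 0
        if (!any(act)) next
        wxv <- numeric(n); wbv <- numeric(n)
        kx <- act & k > 0
        wxv[kx] <- wx(k[kx], m[kx])
        kb <- act & m > 0
        wbv[kb] <- wb(k[kb], m[kb])
        phi[, J] <- phi[, J] + val * (M1 * wxv - M2 * wbv)
      }
    }
  }
  list(values = phi / (length(forest$trees) * nb),
       base_value = mean(forest_predict(forest, background)))
}

#' Exact Shapley attributions by subset enumeration
#'
#' Evaluates the coalition game directly: for every subset of feature groups,
#' the model is scored on hybrid rows taking in-coalition groups from the
#' explained row and the rest from each background row, and Shapley values
#' are assembled from the weighted marginal contributions. Exponential in the
#' number of groups (guarded at `max_groups`), exact for any model, and in
#' probability space whenever the scorer returns probabilities. Grouping
#' one-hot columns into their source feature keeps the group count small.
#'
#' @param score_fun `function(matrix) -> probabilities`.
#' @param x Rows to explain (numeric matrix).
#' @param background Background rows (numeric matrix, same columns).
#' @param groups Named list mapping group name -> column indices.
#' @param max_groups Safety cap on the number of groups (default 15).
#' @return List with `values` (rows x groups) and `base_value`.
#' @export
shap_exact <- function(score_fun, x, background, groups, max_groups = 15) {
  x <- as.matrix(x); background <- as.matrix(background)
  M <- length(groups)
  if (M > max_groups) stop("subset enumeration over ", M,
                           " groups exceeds max_groups = ", max_groups)
  n <- nrow(x); nb <- nrow(background)
  nS <- bitwShiftL(1L, M)
  V <- matrix(0, n, nS)
  big_bg <- background[rep(seq_len(nb), times = n), , drop = FALSE]
  rows_of <- rep(seq_len(n), each = nb)
  for (S in 0:(nS - 1L)) {
    hyb <- big_bg
    for (g in seq_len(M)) {
      if (bitwAnd(S, bitwShiftL(1L, g - 1L)) > 0) {
        cols <- groups[[g]]
        hyb[, cols] <- x[rows_of, cols, drop = FALSE]
      }
    }
    V[, S + 1L] <- as.numeric(rowsum(score_fun(hyb), rows_of)) / nb
  }
  popcount <- vapply(0:(nS - 1L), function(S) sum(bitwAnd(S, bitwShiftL(1L, 0:(M - 1L))) > 0), integer(1))
  w <- exp(lgamma(popcount + 1) + lgamma(M - popcount) - lgamma(M + 1))
  phi <- matrix(0, n, M, dimnames = list(NULL, names(groups)))
  for (g in seq_len(M)) {
    bit <- bitwShiftL(1L, g - 1L)
    without <- which(bitwAnd(0:(nS - 1L), bit) == 0L)
    for (S in without) {
      phi[, g] <- phi[, g] + w[S] * (V[, S + bit] - V[, S])
    }
  }
  list(values = phi, base_value = mean(V[, 1]))
}

# Internal: a probability scorer for any supported model object.
score_function <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "nanotox_model")) return(function(x) predict(model, x))
  if (inherits(model, "nanotox_stack")) return(function(x) predict(model, x))
  if (inherits(model, "nanotox_forest")) return(function(x) forest_predict(model, x))
  stop("unsupported model type for scoring: ", paste(class(model), collapse = "/"))
}

#' Per-sample feature attributions for a fitted model
#'
#' Produces additive attributions in probability space that satisfy local
#' accuracy (base value + attribution sum = predicted probability). For
#' probability-forest backends (random forest, extra trees) the exact
#' polynomial tree-path algorithm runs at the encoded-column level; for all
#' other models (boosted trees, stacks, arbitrary scorers) exact subset
#' enumeration runs at the original-feature level, where the group count is
#' small.
#'
#' @param model A `nanotox_model`, `nanotox_stack`, `nanotox_forest`, or
#'   scoring function.
#' @param mat A `nanotox_matrix` of rows to explain.
#' @param background Optional background `nanotox_matrix` or matrix; defaults
#'   to up to `n_background` rows sampled from `mat`.
#' @param method `"auto"`, `"tree"` (tree-path, column level) or `"exact"`
#'   (enumeration, feature level).
#' @param n_background Background sample size (default 64).
#' @param seed Seed for the background sample.
#' @return Object of class `attribution_table`: `values`, `base_value`,
#'   `level` (`"column"` or `"feature"`), `schema`, `row_ids`.
#' @export
attribute <- function(model, mat, background = NULL,
                      method = c("auto", "tree", "exact"),
                      n_background = 64, seed = 3) {
  method <- match.arg(method)
  x <- mat$x
  bg <- if (is.null(background)) {
    idx <- with_seed(seed, sample(nrow(x), min(n_background, nrow(x))))
    x[idx, , drop = FALSE]
  } else if (inherits(background, "nanotox_matrix")) background$x else as.matrix(background)

  is_forest_backed <- inherits(model, "nanotox_forest") ||
    (inherits(model, "nanotox_model") && inherits(model$model, "ranger"))
  if (method == "auto") method <- if (is_forest_backed) "tree" else "exact"

  if (method == "tree") {
    forest <- if (inherits(model, "nanotox_forest")) model
      else if (inherits(model, "nanotox_model") && inherits(model$model, "ranger"))
        forest_from_ranger(model$model, colnames(x))
      else stop("tree-path attribution needs a probability-forest model")
    res <- shap_tree(forest, x, bg)
    level <- "column"
  } else {
    fmap <- column_feature_map(mat$schema)
    feats <- unique(unname(fmap))
    groups <- lapply(feats, function(f) which(unname(fmap) == f))
    names(groups) <- feats
    res <- shap_exact(score_function(model), x, bg, groups)
    level <- "feature"
  }
  structure(list(values = res$values, base_value = res$base_value,
                 level = level, schema = mat$schema, row_ids = mat$row_ids),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat("Attribution table: ", nrow(x$values), " samples x ", ncol(x$values),
      " ", x$level, "s, base value ", format(x$base_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Group attributions over one-hot columns and rank features
#'
#' Sums each sample's attributions over the encoded columns of every original
#' feature (a signed sum, which preserves the per-sample total exactly), then
#' ranks features by global importance, the mean absolute grouped value.
#' Ties in importance break alphabetically.
#'
#' @param table An `attribution_table`.
#' @param schema The feature schema; defaults to the table's.
#' @return Object of class `grouped_attribution`: `values` (samples x
#'   features), `importance` (named, descending), `ranking` (feature names).
#' @export
group_and_rank <- function(table, schema = table$schema) {
  if (table$level == "feature") {
    grouped <- table$values
  } else {
    fmap <- column_feature_map(schema)
    unmapped <- setdiff(colnames(table$values), names(fmap))
    if (length(unmapped)) stop("unmapped column(s): ",
                               paste(unmapped, collapse = ", "))
    feats <- unique(unname(fmap))
    grouped <- vapply(feats, function(f) {
      cols <- names(fmap)[unname(fmap) == f]
      rowSums(table$values[, cols, drop = FALSE])
    }, numeric(nrow(table$values)))
    if (nrow(table$values) == 1) grouped <- matrix(grouped, nrow = 1,
                                                   dimnames = list(NULL, feats))
  }
  importance <- colMeans(abs(grouped))
  ord <- order(-importance, names(importance))
  structure(list(values = grouped, importance = importance[ord],
                 ranking = names(importance)[ord],
                 base_value = table$base_value, row_ids = table$row_ids),
            class = "grouped_attribution")
}

#' @export
print.grouped_attribution <- function(x, ...) {
  cat("Feature importance (mean |attribution|):\n")
  for (f in x$ranking)
    cat(sprintf("  %-16s %.5f\n", f, x$importance[f]))
  invisible(x)
}

#' Cross-model rank consensus
#'
#' Pairwise Spearman rank correlations of per-model feature importance
#' vectors. All models must cover the same feature set.
#'
#' @param importances Named list of importance vectors (or
#'   `grouped_attribution` objects), one per model.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
consensus <- function(importances) {
  if (length(importances) < 2) stop("need at least 2 models for a consensus")
  vecs <- lapply(importances, function(v) {
    if (inherits(v, "grouped_attribution")) v <- v$importance
    v[order(names(v))]
  })
  feats <- names(vecs[[1]])
  for (v in vecs) if (!identical(names(v), feats))
    stop("models have mismatched feature sets")
  m <- do.call(cbind, vecs)
  cor(m, method = "spearman")
}

#' Per-level attribution summary for a categorical feature
#'
#' Restricts the grouped attributions of one categorical feature to the
#' samples carrying each level and summarizes each level by its median (SHAP
#' distributions are typically non-normal). The full per-level distributions
#' are returned for box plotting. Levels with no samples are omitted with a
#' warning.
#'
#' @param grouped A `grouped_attribution`.
#' @param mat The `nanotox_matrix` the attributions were computed on.
#' @param feature Categorical feature name.
#' @return Data frame of `level`, `median_attribution`, `n`; the per-level
#'   value lists are attached as the `distribution` attribute.
#' @export
categorical_summary <- function(grouped, mat, feature) {
  if (!feature %in% mat$schema$categorical) stop("'", feature,
                                                 "' is not categorical")
  lev <- decode(mat)[[feature]]
  vals <- grouped$values[, feature]
  known <- names(mat$schema$category_levels[[feature]])
  absent <- setdiff(known, unique(lev))
  if (length(absent)) warning("level(s) with zero samples omitted: ",
                              paste(absent, collapse = ", "))
  present <- intersect(known, unique(lev))
  dist <- lapply(present, function(l) vals[lev == l])
  names(dist) <- present
  out <- data.frame(level = present,
                    median_attribution = vapply(dist, median, numeric(1)),
                    n = vapply(dist, length, integer(1)),
                    row.names = NULL)
  attr(out, "distribution") <- dist
  out
}
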