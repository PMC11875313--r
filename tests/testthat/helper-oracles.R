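# Independent brute-force references used as oracles. These are written
# naively (explicit loops, literal formulas) and share no code with the
# package implementations they check.

ref_confusion <- function(labels, scores, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    if (pred && labels[i] == 0) fp <- fp + 1L
    if (!pred && labels[i] == 0) tn <- tn + 1L
    if (!pred && labels[i] == 1) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

ref_scalars <- function(cm) {
  div <- function(a, b) if (b == 0) 0 else a / b
  sens <- div(cm$TP, cm$TP + cm$FN)
  spec <- div(cm$TN, cm$TN + cm$FP)
  prec <- div(cm$TP, cm$TP + cm$FP)
  den2 <- as.double(cm$TP + cm$FP) * (cm$TP + cm$FN) *
    (cm$TN + cm$FP) * (cm$TN + cm$FN)
  list(accuracy = div(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN),
       sensitivity = sens, specificity = spec, precision = prec,
       f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
       mcc = if (den2 == 0) 0 else
         (as.double(cm$TP) * cm$TN - as.double(cm$FP) * cm$FN) / sqrt(den2),
       balanced_accuracy = (sens + spec) / 2)
}

# Average precision: step sum of precision * delta-recall over descending
# distinct thresholds, each point recomputed by explicit counting.
ref_average_precision <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  ap <- 0; prev_recall <- 0
  for (t in ths) {
    cm <- ref_confusion(labels, scores, t)
    recall <- cm$TP / P
    precision <- if (cm$TP + cm$FP == 0) 1 else cm$TP / (cm$TP + cm$FP)
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# ROC AUC as pairwise concordance: ties count one half.
ref_roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (if (p > n) 1 else if (p == n) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# Exhaustive F1 scan; returns the best F1 and the largest maximizing
# threshold among candidates (distinct scores plus a sentinel).
ref_best_f1 <- function(labels, scores) {
  cands <- c(sort(unique(scores)), max(scores) + 1)
  best_f1 <- -1; best_t <- NA
  for (t in cands) {
    f1 <- ref_scalars(ref_confusion(labels, scores, t))$f1
    if (f1 > best_f1 || (f1 == best_f1 && t > best_t)) {
      best_f1 <- f1; best_t <- t
    }
  }
  list(f1 = best_f1, threshold = best_t)
}

# Brute-force interventional Shapley: the subset-sum definition evaluated
# literally. v(S) = mean over background rows of f(x with S's columns, rest
# from background). groups: list of column-index vectors.
brute_shapley <- function(score_fun, x_row, background, groups) {
  M <- length(groups)
  v <- function(S) {           # S: integer subset of 1:M
    tot <- 0
    for (b in seq_len(nrow(background))) {
      z <- background[b, ]
      for (g in S) z[groups[[g]]] <- x_row[groups[[g]]]
      tot <- tot + score_fun(matrix(z, nrow = 1))
    }
    tot / nrow(background)
  }
  phi <- numeric(M)
  others <- function(i) setdiff(seq_len(M), i)
  for (i in seq_len(M)) {
    for (k in 0:(M - 1)) {
      sets <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(others(i), k), 2)
      w <- factorial(k) * factorial(M - k - 1) / factorial(M)
      for (S in sets) phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  phi
}

# A tiny hand-specified tree in the package's node-table format.
make_tree <- function(feature, split, left, right, value) {
  data.frame(feature = feature, split = split, left = left, right = right,
             value = value)
}

# A classifier spec that memorizes its training rows and scores 1 for any
# row it has seen before, 0 otherwise. Used as a leakage canary: any
# out-of-fold score of 1 means a training row leaked into evaluation.
spec_memorizer <- function() {
  classifier_spec(
    name = "memorizer",
    fit = function(x, y, params = list(), seed = NULL) {
      list(keys = apply(x, 1, paste, collapse = "\r"))
    },
    predict_prob = function(model, x) {
      as.numeric(apply(x, 1, paste, collapse = "\r") %in% model$keys)
    })
}

# Small fast hyperparameter set for boosted-tree fits in tests.
fast_gbt_params <- list(max_depth = 3, eta = 0.3, max_rounds = 200,
                        patience = 20)

# Reference PBPK scenario: MPS-dominated hepatic uptake with modest renal
# elimination, the canonical inorganic-nanoparticle disposition pattern.
ref_pbpk_truth <- function() {
  pbpk_params(P = c(liver = 20, spleen = 8, lungs = 2, kidneys = 1.5,
                    others = 0.4),
              k_bile = 0.05, k_urine = 0.1)
}
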