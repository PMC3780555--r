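# Random-forest evaluation under k-fold cross-validation, the confusion-
# matrix metric suite (ACC, SP, SN, MCC) plus ROC AUC, and the incremental
# feature selection (IFS) driver that evaluates nested prefixes of the mRMR
# list and picks the prefix length maximizing MCC.

#' Random-forest configuration
#'
#' Defaults mirror the classic small-forest setup: 10 unpruned trees, with
#' `floor(log2(M)) + 1` candidate features per node (computed at fit time
#' when `m_try` is `NULL`).
#'
#' @param n_trees Number of trees (>= 1).
#' @param m_try Candidate features per node, or `NULL` for the log2 rule.
#' @param seed Master integer seed for tree bootstraps and feature draws.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 10, m_try = NULL, seed = 1) {
  stopifnot(n_trees >= 1, is.null(m_try) || m_try >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 m_try = if (is.null(m_try)) NULL else as.integer(m_try),
                 seed = as.integer(seed)),
            class = "forest_config")
}

resolve_mtry <- function(config, M) {
  m <- if (is.null(config$m_try)) floor(log2(M)) + 1 else config$m_try
  max(1L, min(as.integer(m), M))
}

# Seed for the forest trained on fold `fold` of subset size `k`, derived from
# the master seed by a fixed counter scheme so adding subset sizes never
# perturbs earlier rows. Kept inside 32-bit signed range.
rf_seed <- function(master, k, fold) {
  as.integer((as.double(master) + 100003 * k + fold) %% 2147483647)
}

#' Fit a random forest
#'
#' Bootstrap of n rows per tree, `m_try` random candidate features per node,
#' unpruned binary trees with Gini splits, majority vote. The out-of-bag
#' error is computed for reference but never used for model selection.
#'
#' @param x Numeric matrix (rows = samples).
#' @param y Binary labels (0/1), length `nrow(x)`.
#' @param config A [forest_config()].
#' @return Object of class `drug_rf`.
#' @export
rf_fit <- function(x, y, config = forest_config()) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  fit <- .rf_fit_cpp(x, as.integer(y), config$n_trees,
                     resolve_mtry(config, ncol(x)), config$seed)
  class(fit) <- "drug_rf"
  fit
}

#' Positive-vote fractions of a fitted forest
#'
#' Per-row fraction of trees voting for the positive class; with 10 trees
#' this takes 11 discrete values and serves as the ROC score.
#'
#' @param fit A `drug_rf` object.
#' @param x Numeric matrix with the same columns used at fit time.
#' @return Numeric vector in \[0, 1\].
#' @export
rf_votes <- function(fit, x) {
  stopifnot(inherits(fit, "drug_rf"), is.matrix(x))
  .rf_votes_cpp(unclass(fit), x)
}

#' @export
print.drug_rf <- function(x, ...) {
  cat(sprintf("<drug_rf trees=%d mtry=%d oob_error=%.4f>\n",
              x$n_trees, x$mtry, x$oob_error))
  invisible(x)
}

#' Confusion-matrix metrics and ROC AUC
#'
#' Computes TP/TN/FP/FN and the derived accuracy, specificity
#' `TN / (TN + FP)`, sensitivity `TP / (TP + FN)`, and Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))` with 0
#' substituted when the denominator vanishes. AUC is the normalized area
#' under the ROC over all thresholds of `scores`, computed by the midrank
#' (trapezoid) convention; constant scores give 0.5, and a single-class label
#' vector gives `NA`.
#'
#' @param labels Binary vector (1 = positive).
#' @param predictions Binary vector of the same length.
#' @param scores Optional numeric vector (higher = more positive) for AUC.
#' @return Object of class `confusion_metrics`: tp, tn, fp, fn, acc, sp, sn,
#'   mcc, auc.
#' @export
compute_metrics <- function(labels, predictions, scores = NULL) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length")
  }
  if (!is.null(scores) && length(scores) != length(labels)) {
    stop("labels and scores differ in length")
  }
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  stopifnot(all(labels %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  n <- tp + tn + fp + fn
  acc <- (tp + tn) / n
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  den <- as.double(tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
  mcc <- if (den > 0) (as.double(tp) * tn - as.double(fp) * fn) / sqrt(den)
         else 0
  auc <- if (is.null(scores)) NA_real_ else roc_auc(labels, scores)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = acc, sp = sp, sn = sn, mcc = mcc, auc = auc),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics TP=%d TN=%d FP=%d FN=%d | ACC=%.4f SP=%.4f SN=%.4f MCC=%.4f AUC=%s>\n",
    x$tp, x$tn, x$fp, x$fn, x$acc, x$sp, x$sn, x$mcc,
    ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' ROC AUC by the midrank convention
#'
#' Equivalent to the trapezoid area under the ROC curve with tied scores
#' sharing credit (Mann-Whitney statistic on midranks). `NA` when only one
#' class is present.
#'
#' @param labels Binary vector (1 = positive).
#' @param scores Numeric vector, higher = more positive.
#' @return Number in \[0, 1\], or `NA`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity vs 1 - specificity at every distinct score threshold,
#' including the (0,0) and (1,1) endpoints, for plotting.
#'
#' @param labels Binary vector (1 = positive).
#' @param scores Numeric vector.
#' @return data.table with columns threshold, fpr, tpr.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.integer(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  data.table::data.table(threshold = c(Inf, thr), fpr = c(0, fpr),
                         tpr = c(0, tpr))
}

# Fold assignment: a seeded uniform-random partition into near-equal
# portions (sizes differ by at most 1). Optionally stratified by class.
cv_folds <- function(labels, folds, cv_seed, stratified = FALSE) {
  n <- length(labels)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  local_seed(cv_seed, {
    if (stratified) {
      assign_out <- integer(n)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        assign_out[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      assign_out
    } else {
      sample(rep_len(seq_len(folds), n))
    }
  })
}

#' Cross-validated random-forest evaluation of a feature subset
#'
#' Partitions the rows uniformly at random (seeded) into `folds` near-equal
#' portions; each portion is tested once with the rest as training data, so
#' every row is predicted exactly once. The per-row score is the fraction of
#' trees voting positive; the predicted class is positive when that fraction
#' exceeds 0.5 (a 5-5 tie with 10 trees goes negative). Metrics are pooled
#' over all rows.
#'
#' @param features Numeric matrix with column names, or `pair_features`.
#' @param labels Binary vector (ignored for `pair_features` input).
#' @param feature_subset Ordered character vector of column names to use.
#' @param folds Number of folds (default 5).
#' @param config A [forest_config()]; the forest seed for fold f is derived
#'   from `config$seed` and `k_index` via a fixed counter scheme.
#' @param cv_seed Seed for the fold partition.
#' @param stratified Stratify the partition by class (off by default; the
#'   plain protocol separates the data "equally at random").
#' @param k_index Subset-size index used in the per-(k, fold) seed
#'   derivation; the IFS driver passes the prefix length.
#' @return A `confusion_metrics` object with attribute `"scores"` (per-row
#'   vote fractions) and `"fold"` (fold assignment).
#' @export
crossval <- function(features, labels = NULL, feature_subset, folds = 5,
                     config = forest_config(), cv_seed = 1,
                     stratified = FALSE, k_index = 0L) {
  if (inherits(features, "pair_features")) {
    labels <- features$labels
    features <- features$features
  }
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  if (!all(feature_subset %in% colnames(features))) {
    stop("feature subset contains unknown columns: ",
         paste(utils::head(setdiff(feature_subset, colnames(features)), 5),
               collapse = ", "))
  }
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  x <- features[, feature_subset, drop = FALSE]
  y <- as.integer(labels)
  fold <- cv_folds(y, folds, cv_seed, stratified)
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    test <- fold == f
    cfg <- config
    cfg$seed <- rf_seed(config$seed, k_index, f)
    fit <- rf_fit(x[!test, , drop = FALSE], y[!test], cfg)
    scores[test] <- rf_votes(fit, x[test, , drop = FALSE])
  }
  pred <- as.integer(scores > 0.5)
  m <- compute_metrics(y, pred, scores)
  attr(m, "scores") <- scores
  attr(m, "fold") <- fold
  m
}

#' Incremental feature selection over mRMR prefixes
#'
#' Evaluates [crossval()] on the first k features of `mrmr_list` for
#' k = 1..k_max, reusing the identical fold partition (same `cv_seed`) for
#' every k, and selects the k maximizing MCC (smallest k on ties).
#'
#' @param features Numeric matrix or `pair_features`.
#' @param labels Binary vector (ignored for `pair_features`).
#' @param mrmr_list Ordered feature names (the mRMR list).
#' @param k_max Largest prefix length to evaluate (<= length(mrmr_list)).
#' @param folds,config,cv_seed,stratified Passed to [crossval()].
#' @return Object of class `ifs_result`: `rows` (data.table k, tp, tn, fp,
#'   fn, acc, sp, sn, mcc, auc), `optimal_k`, `optimal_features`, and
#'   `optimal_scores` (per-row vote fractions at the optimum, for ROC plots).
#' @export
run_ifs <- function(features, labels = NULL, mrmr_list,
                    k_max = length(mrmr_list), folds = 5,
                    config = forest_config(), cv_seed = 1,
                    stratified = FALSE) {
  if (inherits(features, "pair_features")) {
    labels <- features$labels
    features <- features$features
  }
  stopifnot(k_max >= 1, k_max <= length(mrmr_list))
  rows <- vector("list", k_max)
  scores_by_k <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    m <- crossval(features, labels, mrmr_list[seq_len(k)], folds = folds,
                  config = config, cv_seed = cv_seed,
                  stratified = stratified, k_index = k)
    rows[[k]] <- data.table::data.table(
      k = k, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
      acc = m$acc, sp = m$sp, sn = m$sn, mcc = m$mcc, auc = m$auc)
    scores_by_k[[k]] <- attr(m, "scores")
  }
  rows <- data.table::rbindlist(rows)
  optimal_k <- rows[which.max(mcc), k]  # which.max takes the first maximum
  structure(list(rows = rows, optimal_k = optimal_k,
                 optimal_features = mrmr_list[seq_len(optimal_k)],
                 optimal_scores = scores_by_k[[optimal_k]],
                 labels = as.integer(labels)),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  best <- x$rows[k == x$optimal_k]
  cat(sprintf(
    "<ifs_result k=1..%d | optimal k=%d MCC=%.4f ACC=%.4f AUC=%s>\n",
    nrow(x$rows), x$optimal_k, best$mcc, best$acc,
    ifelse(is.na(best$auc), "NA", sprintf("%.4f", best$auc))))
  invisible(x)
}

#' Write the IFS metric table as TSV (k, ACC, SP, SN, MCC, AUC)
#' @param ifs An `ifs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_table <- function(ifs, path) {
  stopifnot(inherits(ifs, "ifs_result"))
  data.table::fwrite(ifs$rows, path, sep = "\t")
  invisible(path)
}

#' Plot the IFS curve (MCC vs number of features) as SVG
#' @param ifs An `ifs_result`.
#' @param path Output SVG path.
#' @return `path`, invisibly.
#' @export
plot_ifs_curve <- function(ifs, path) {
  stopifnot(inherits(ifs, "ifs_result"))
  grDevices::svg(path, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(ifs$rows$k, ifs$rows$mcc, type = "l",
       xlab = "number of features", ylab = "MCC", main = "IFS curve")
  graphics::abline(v = ifs$optimal_k, lty = 2)
  invisible(path)
}

#' Plot the ROC curve at the optimal IFS subset as SVG
#' @param ifs An `ifs_result`.
#' @param path Output SVG path.
#' @return `path`, invisibly.
#' @export
plot_roc_curve <- function(ifs, path) {
  stopifnot(inherits(ifs, "ifs_result"))
  pts <- roc_points(ifs$labels, ifs$optimal_scores)
  grDevices::svg(path, width = 5, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(pts$fpr, pts$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity", main = "ROC curve")
  graphics::abline(0, 1, lty = 3)
  invisible(path)
}
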