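# Confusion metrics, ROC AUC, the random forest, cross-validation and IFS.

make_preds <- function(tp, tn, fp, fn) {
  list(labels = c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn)),
       predictions = c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn)))
}

test_that("compute_metrics reproduces hand-checked confusion values", {
  p <- make_preds(50, 50, 0, 0)
  m <- compute_metrics(p$labels, p$predictions)
  expect_equal(c(m$acc, m$sp, m$sn, m$mcc), c(1, 1, 1, 1))

  p <- make_preds(10, 50, 10, 10)
  m <- compute_metrics(p$labels, p$predictions)
  expect_equal(m$mcc, 400 / 1200, tolerance = 1e-12)
  expect_equal(m$acc, 0.75)
  expect_equal(m$sp, 5 / 6, tolerance = 1e-12)
  expect_equal(m$sn, 0.5)
  expect_error(compute_metrics(0:1, c(1, 0, 1)), "differ in length")
})

test_that("metrics match the counting oracle and MCC equals the Pearson correlation", {
  set.seed(21)
  checked <- 0
  while (checked < 100) {
    n <- sample(20:80, 1)
    labels <- sample(0:1, n, replace = TRUE)
    predictions <- sample(0:1, n, replace = TRUE)
    m <- compute_metrics(labels, predictions)
    cnt <- naive_confusion(labels, predictions)
    expect_identical(c(tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn), cnt)
    expect_equal(m$tp + m$tn + m$fp + m$fn, n)
    expect_equal(m$acc, (cnt["tp"] + cnt["tn"]) / n, ignore_attr = TRUE)
    if (sd(labels) > 0 && sd(predictions) > 0) {
      expect_equal(m$mcc, cor(labels, predictions), tolerance = 1e-12)
    } else {
      expect_equal(m$mcc, 0)  # 0/0 convention
    }
    checked <- checked + 1
  }
})

test_that("AUC: constant scores give 0.5, monotone transforms change nothing", {
  labels <- rep(c(1, 0), times = c(20, 80))
  expect_equal(roc_auc(labels, rep(0.3, 100)), 0.5)
  set.seed(4)
  scores <- runif(100)
  a <- roc_auc(labels, scores)
  expect_equal(roc_auc(labels, exp(scores)), a, tolerance = 1e-12)
  expect_equal(roc_auc(labels, 100 * scores - 3), a, tolerance = 1e-12)
  expect_true(is.na(roc_auc(rep(1, 5), runif(5))))
  # perfect ranking
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  pts <- roc_points(labels, scores)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("the forest separates separable data, is deterministic, and reports OOB", {
  set.seed(8)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- cbind(signal = y * 10 + rnorm(n, sd = 0.1),
             noise = rnorm(n))
  cfg <- forest_config(n_trees = 10, seed = 5)
  fit <- rf_fit(x, y, cfg)
  votes <- rf_votes(fit, x)
  expect_true(all(votes >= 0 & votes <= 1))
  expect_equal(as.integer(votes > 0.5), y)
  expect_true(fit$oob_error >= 0 && fit$oob_error < 0.2)
  # default mtry rule: floor(log2 M) + 1
  expect_equal(fit$mtry, floor(log2(2)) + 1)
  fit2 <- rf_fit(x, y, cfg)
  expect_identical(rf_votes(fit2, x), votes)
  expect_identical(fit2$trees, fit$trees)
  # a different seed draws different bootstraps (votes may still agree on
  # perfectly separable data, but the trees cannot)
  fit3 <- rf_fit(x, y, forest_config(n_trees = 10, seed = 6))
  expect_false(identical(fit3$trees, fit$trees))
})

test_that("CV partitions are near-equal, disjoint and exhaustive; rows tested once", {
  set.seed(2)
  n <- 103
  y <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
  x <- cbind(a = rnorm(n), b = rnorm(n), lab = as.numeric(y))
  colnames(x) <- c("a", "b", "lab")
  m <- crossval(x, y, c("a", "b"), folds = 5, cv_seed = 3)
  fold <- attr(m, "fold")
  expect_equal(sort(unique(fold)), 1:5)
  expect_lte(diff(range(table(fold))), 1)
  expect_equal(m$tp + m$tn + m$fp + m$fn, n)
  # a feature equal to the label separates perfectly on any split
  m2 <- crossval(x, y, "lab", folds = 5, cv_seed = 3)
  expect_equal(m2$mcc, 1)
  expect_error(crossval(x, y, "zz"), "unknown columns")
})

test_that("crossval and run_ifs are bit-reproducible for fixed seeds", {
  set.seed(12)
  n <- 90
  y <- sample(0:1, n, replace = TRUE)
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 1] <- x[, 1] + y * 2
  a <- crossval(x, y, colnames(x), cv_seed = 9,
                config = forest_config(seed = 4))
  b <- crossval(x, y, colnames(x), cv_seed = 9,
                config = forest_config(seed = 4))
  expect_identical(attr(a, "scores"), attr(b, "scores"))
  expect_equal(unclass(a)[c("tp", "tn", "fp", "fn", "mcc", "auc")],
               unclass(b)[c("tp", "tn", "fp", "fn", "mcc", "auc")])

  ifs1 <- run_ifs(x, y, colnames(x), k_max = 4, cv_seed = 9,
                  config = forest_config(seed = 4))
  ifs2 <- run_ifs(x, y, colnames(x), k_max = 4, cv_seed = 9,
                  config = forest_config(seed = 4))
  expect_identical(ifs1$rows, ifs2$rows)
  # the per-(k, fold) seed scheme: row k is unchanged by a larger k_max
  ifs3 <- run_ifs(x, y, colnames(x), k_max = 6, cv_seed = 9,
                  config = forest_config(seed = 4))
  expect_identical(ifs1$rows, ifs3$rows[k <= 4])
})

test_that("run_ifs covers k = 1..k_max and finds a trivial optimum", {
  set.seed(13)
  n <- 80
  y <- sample(0:1, n, replace = TRUE)
  x <- cbind(lab = as.numeric(y), n1 = rnorm(n), n2 = rnorm(n))
  ifs <- run_ifs(x, y, c("lab", "n1", "n2"), k_max = 3, cv_seed = 2)
  expect_identical(ifs$rows$k, 1:3)
  expect_equal(ifs$optimal_k, 1)
  expect_equal(ifs$rows$mcc[1], 1)
  expect_identical(ifs$optimal_features, "lab")
  # artifacts
  dir <- withr::local_tempdir()
  write_ifs_table(ifs, file.path(dir, "ifs.tsv"))
  expect_identical(data.table::fread(file.path(dir, "ifs.tsv"))$k, 1:3)
  plot_ifs_curve(ifs, file.path(dir, "ifs.svg"))
  plot_roc_curve(ifs, file.path(dir, "roc.svg"))
  expect_true(all(file.exists(file.path(dir, c("ifs.svg", "roc.svg")))))
})
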