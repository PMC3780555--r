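# Discretization, mutual information and the MaxRel / mRMR rankings.

test_that("discretize follows the mean +/- sd three-state rule", {
  expect_identical(discretize(c(0, 0, 0, 0)), rep(0L, 4))
  # mean 1, sample sd sqrt(10) ~ 3.16: only the 10 exceeds mean + sd
  expect_identical(discretize(c(10, rep(0, 9))), c(1L, rep(0L, 9)))
  x <- c(-50, 1, 2, 3, 50)
  expect_identical(discretize(x), c(-1L, 0L, 0L, 0L, 1L))
  # pointwise rule => permutation equivariance
  set.seed(1)
  z <- rnorm(40)
  p <- sample(40)
  expect_identical(discretize(z[p]), discretize(z)[p])
  # matches the independent implementation on random draws
  for (s in 1:10) {
    set.seed(s)
    v <- rnorm(30, sd = sample(1:5, 1))
    expect_identical(discretize(v), disc_oracle(v))
  }
})

test_that("mutual_information reproduces closed-form values", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(1, 1, 1, 1)), 0)
  expect_equal(mutual_information(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI is symmetric, non-negative, and matches the table() oracle", {
  set.seed(7)
  for (rep in 1:30) {
    x <- sample(-1:1, 50, replace = TRUE)
    y <- sample(0:1, 50, replace = TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
    expect_gte(mutual_information(x, y), 0)
    expect_equal(mutual_information(x, y), mi_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("a label-copy feature tops both lists and noise trails", {
  set.seed(5)
  y <- rep(c(1L, 0L), times = c(10, 50))          # imbalanced, like 121:605
  X <- cbind(f1 = y * 10, f2 = runif(60))
  rk <- rank_features(X, y)
  expect_identical(rk$maxrel, c("f1", "f2"))
  expect_identical(rk$mrmr, c("f1", "f2"))
  expect_identical(rk$maxrel[1], rk$mrmr[1])
})

test_that("an exact copy of the first pick is deferred behind a weaker independent feature", {
  # f2 duplicates f1; f3 is equally label-associated but nearly independent
  # of f1 (their discretized patterns overlap in one row of eight). After
  # picking f1, f2's redundancy is H(f1) = 0.811 bits while f3's is 0.074,
  # so the greedy step promotes f3: 0.311 - 0.074 > 0.311 - 0.811. The same
  # ordering is cross-checked against the independent greedy implementation.
  y <- rep(c(1L, 0L), each = 4)
  f1 <- c(10, 10, 0, 0, 0, 0, 0, 0)
  f3 <- c(10, 0, 10, 0, 0, 0, 0, 0)
  X <- cbind(f1 = f1, f2 = f1, f3 = f3)
  rk <- rank_features(X, y)
  oracle <- naive_mrmr(X, y)
  expect_identical(rk$maxrel, oracle$maxrel)
  expect_identical(rk$mrmr, oracle$mrmr)
  expect_lt(match("f3", rk$mrmr), match("f2", rk$mrmr))
})

test_that("rank_features agrees with the independent greedy oracle on random matrices", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 24
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    rk <- rank_features(X, y)
    oracle <- naive_mrmr(X, y)
    expect_identical(rk$maxrel, oracle$maxrel, label = paste("seed", seed))
    expect_identical(rk$mrmr, oracle$mrmr, label = paste("seed", seed))
    expect_equal(unname(rk$relevance), unname(oracle$relevance),
                 tolerance = 1e-12)
  }
})

test_that("both lists are permutations, share their head, and survive pure noise", {
  set.seed(9)
  X <- matrix(rnorm(80 * 12), 80, 12,
              dimnames = list(NULL, sprintf("n%02d", 1:12)))
  y <- rep(0:1, 40)
  rk <- rank_features(X, y)
  expect_setequal(rk$maxrel, colnames(X))
  expect_setequal(rk$mrmr, colnames(X))
  expect_false(anyDuplicated(rk$mrmr) > 0)
  expect_identical(rk$maxrel[1], rk$mrmr[1])
  expect_identical(rk$maxrel,
                   colnames(X)[order(-rk$relevance, seq_len(ncol(X)))])
  # near-zero relevance on iid noise
  expect_lt(max(rk$relevance), 0.25)
})

test_that("planted pair-level signal is fully recovered in the maxrel head", {
  # Exactly 3 features carry label signal (chemical shift + cross-target
  # interaction boost); all must land in the top 3k = 9 of maxrel in >= 9/10
  # seeds. Pathway co-enrichment is off: its per-drug channel is checked
  # separately (see the acceptance suite and the methods vignette).
  hits <- 0
  for (seed in 1:10) {
    cfg <- synth_config(n_drugs = 60, n_proteins = 600, n_pathways = 60,
                        n_positives = 40, chem_shift = 500,
                        cross_ppi_boost = 0.3, seed = seed)
    sd <- synth_generate(cfg)
    expect_identical(sd$signal_features,
                     c("chem", "ppi_cross_max", "ppi_cross_mean"))
    pr <- profile_all(sd$drugs, sd$ppi, sd$annotation)
    pf <- build_matrix(sd$labels, sd$drugs, sd$chem, sd$ppi, pr)
    rk <- rank_features(pf)
    ranks <- match(sd$signal_features, rk$maxrel)
    if (all(ranks <= 9)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("single-class labels and ranked-list output are handled", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(rank_features(X, rep(1, 10)), "single class")
  rk <- rank_features(X, rep(c(0, 1), 5))
  prefix <- file.path(withr::local_tempdir(), "ranked")
  paths <- write_ranked_lists(rk, prefix)
  mx <- data.table::fread(paste0(prefix, "_maxrel.tsv"))
  mr <- data.table::fread(paste0(prefix, "_mrmr.tsv"))
  expect_identical(mx$feature, rk$maxrel)
  expect_identical(mr$feature, rk$mrmr)
})
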