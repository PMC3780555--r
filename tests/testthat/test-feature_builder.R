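# Symmetric pair encoding: spec'd examples, swap invariance, and equivalence
# with the brute-force enumerator on random instances.

test_that("chemical_feature is a symmetric zero-default lookup", {
  chem <- score_table("d1", "d2", 800, "chemical")
  expect_equal(chemical_feature("d1", "d2", chem), 800)
  expect_equal(chemical_feature("d2", "d1", chem), 800)
  expect_identical(chemical_feature("d1", "d9", chem), 0)
})

test_that("cross_group_features: max and mean over cross pairs with zero default", {
  ppi <- score_table("A", "B", 900, "protein")
  expect_equal(cross_group_features("A", "B", ppi),
               c(max = 900, mean = 900))
  ppi2 <- score_table("A", "B", 600, "protein")
  expect_equal(cross_group_features("A", c("B", "C"), ppi2),
               c(max = 600, mean = 300))  # (600 + 0) / 2
  expect_equal(cross_group_features(c("X", "Y"), c("Z"),
                                    score_table(kind = "protein")),
               c(max = 0, mean = 0))
  # shared target: the (T, T) self pair is excluded from the divisor
  ppi3 <- score_table("A", "B", 400, "protein")
  expect_equal(cross_group_features(c("A", "B"), c("B"), ppi3),
               c(max = 400, mean = 400))
  expect_error(cross_group_features(character(0), "A", ppi), "empty")
})

test_that("within_group_features: singleton convention and symmetry", {
  ppi <- score_table("A", "B", 400, "protein")
  expect_equal(within_group_features(c("A", "B"), "C", ppi),
               c(sum_max = 400, sum_mean = 400,
                 absdiff_max = 400, absdiff_mean = 400))
  expect_equal(within_group_features("A", "B", ppi),
               c(sum_max = 0, sum_mean = 0,
                 absdiff_max = 0, absdiff_mean = 0))
  expect_identical(within_group_features(c("A", "B"), "C", ppi),
                   within_group_features("C", c("A", "B"), ppi))
})

test_that("pathway_features concatenates sums then absolute differences", {
  e1 <- c(pw1 = 1, pw2 = 2); e2 <- c(pw1 = 3, pw2 = 0)
  expect_equal(unname(pathway_features(e1, e2)), c(4, 2, 2, 2))
  expect_equal(unname(pathway_features(e1, e1)[3:4]), c(0, 0))
  expect_error(pathway_features(e1, c(pw2 = 1, pw1 = 2)), "pathway order")
  # 229 pathways -> 458 enrichment features
  e <- stats::setNames(runif(229), sprintf("pw%03d", 1:229))
  expect_length(pathway_features(e, e), 458)
})

test_that("feature dimension is 7 + 2P and exactly 465 at P = 229", {
  expect_length(pair_feature_names(sprintf("pw%03d", 1:229)), 465)
  inst <- random_instance(2)
  P <- length(inst$annotation$pathways)
  expect_length(pair_feature_names(names(inst$annotation$pathways)),
                7 + 2 * P)
})

test_that("build_matrix matches the brute-force enumerator on random instances", {
  n_instances <- 40  # x5+ pairs each: > 200 pair vectors in total
  total_pairs <- 0
  for (seed in seq_len(n_instances)) {
    inst <- random_instance(seed)
    dr <- names(inst$drugs)
    pos <- data.frame(drug1 = dr[1], drug2 = dr[2])
    labels <- sample_negatives(dr, pos, ratio = 4, seed = seed)
    pr <- profile_all(inst$drugs, inst$ppi, inst$annotation)
    pf <- build_matrix(labels, inst$drugs, inst$chem, inst$ppi, pr)
    expect_identical(colnames(pf$features),
                     pair_feature_names(names(inst$annotation$pathways)))
    for (r in seq_len(nrow(pf$features))) {
      bf <- bf_pair_vector(pf$pairs$drug1[r], pf$pairs$drug2[r],
                           inst$drugs, inst$chem_df, inst$ppi_df,
                           inst$annotation$pathways, inst$N, inst$prot)
      expect_equal(unname(pf$features[r, ]), bf, tolerance = 1e-9,
                   label = sprintf("seed=%d row=%d", seed, r))
      total_pairs <- total_pairs + 1
    }
  }
  expect_gte(total_pairs, 200)
})

test_that("every feature is swap-invariant and non-negative", {
  for (seed in 1:10) {
    inst <- random_instance(seed, n_drugs = 4)
    pr <- profile_all(inst$drugs, inst$ppi, inst$annotation)
    dr <- names(inst$drugs)
    for (i in 1:3) for (j in (i + 1):4) {
      d1 <- dr[i]; d2 <- dr[j]
      v12 <- c(chemical_feature(d1, d2, inst$chem),
               cross_group_features(inst$drugs[[d1]], inst$drugs[[d2]],
                                    inst$ppi),
               within_group_features(inst$drugs[[d1]], inst$drugs[[d2]],
                                     inst$ppi),
               pathway_features(pr[d1, ], pr[d2, ]))
      v21 <- c(chemical_feature(d2, d1, inst$chem),
               cross_group_features(inst$drugs[[d2]], inst$drugs[[d1]],
                                    inst$ppi),
               within_group_features(inst$drugs[[d2]], inst$drugs[[d1]],
                                     inst$ppi),
               pathway_features(pr[d2, ], pr[d1, ]))
      expect_equal(unname(v12), unname(v21), tolerance = 1e-12)
      expect_true(all(v12 >= 0))
    }
  }
})

test_that("build_matrix validates pair membership and round-trips via TSV", {
  inst <- random_instance(5)
  dr <- names(inst$drugs)
  pos <- data.frame(drug1 = dr[1], drug2 = dr[2])
  labels <- sample_negatives(dr, pos, ratio = 3, seed = 5)
  pr <- profile_all(inst$drugs, inst$ppi, inst$annotation)
  pf <- build_matrix(labels, inst$drugs, inst$chem, inst$ppi, pr)
  expect_identical(pf$labels, c(1L, rep(0L, 3)))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(pf, path)
  pf2 <- read_feature_matrix(path)
  expect_equal(pf2$features, pf$features, tolerance = 1e-9)
  expect_identical(pf2$labels, pf$labels)
  expect_identical(as.data.frame(pf2$pairs), as.data.frame(pf$pairs))

  bad <- labels
  bad$positives$drug1[1] <- "ghost"
  expect_error(build_matrix(bad, inst$drugs, inst$chem, inst$ppi, pr),
               "ghost")
})
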