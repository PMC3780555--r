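# Symmetric encoding of an unordered drug pair as 7 + 2P features:
#   1 chemical-interaction score,
#   2 cross-target-group interaction summaries (max, mean),
#   4 within-target-group summaries (sum and |difference| of per-drug max and
#     mean),
#   P pathway-enrichment sums and P absolute differences.
# Every feature is a symmetric function of the two drugs, so the row for
# (d1, d2) is identical to the row for (d2, d1).

#' Canonical feature names for a pathway set
#'
#' Column order is fixed: `chem`, `ppi_cross_max`, `ppi_cross_mean`,
#' `ppi_within_sum_max`, `ppi_within_sum_mean`, `ppi_within_absdiff_max`,
#' `ppi_within_absdiff_mean`, then `sum:<pathway>` for every pathway and
#' `absdiff:<pathway>` for every pathway, in the annotation's sorted order.
#'
#' @param pathway_ids Character vector of pathway ids (already ordered).
#' @return Character vector of length `7 + 2 * length(pathway_ids)`.
#' @export
pair_feature_names <- function(pathway_ids) {
  c("chem", "ppi_cross_max", "ppi_cross_mean",
    "ppi_within_sum_max", "ppi_within_sum_mean",
    "ppi_within_absdiff_max", "ppi_within_absdiff_mean",
    paste0("sum:", pathway_ids), paste0("absdiff:", pathway_ids))
}

#' Chemical-interaction feature of a drug pair
#'
#' The pair's interaction confidence score in the chemical table; 0 when the
#' pair is absent. Symmetric by construction of the table.
#'
#' @param d1,d2 Drug ids.
#' @param chem Chemical [score_table()].
#' @return A number.
#' @export
chemical_feature <- function(d1, d2, chem) {
  score_lookup(chem, d1, d2)
}

#' Cross-target-group interaction features
#'
#' Max and mean of protein-interaction confidence scores over all cross pairs
#' (t1, t2) with t1 in `T1`, t2 in `T2`. Absent pairs contribute 0. Pairs
#' with identical protein on both sides (possible when the drugs share
#' targets) are excluded — a protein's interaction with itself is undefined —
#' and the mean divides by the count of evaluated pairs. If no pair is
#' evaluable the result is (0, 0).
#'
#' @param T1,T2 Non-empty character vectors of target ids.
#' @param ppi Protein [score_table()].
#' @return Named numeric vector `c(max = ..., mean = ...)`.
#' @export
cross_group_features <- function(T1, T2, ppi) {
  T1 <- unique(as.character(T1)); T2 <- unique(as.character(T2))
  if (length(T1) == 0 || length(T2) == 0) stop("empty target set")
  a <- rep(T1, times = length(T2))
  b <- rep(T2, each = length(T1))
  keep <- a != b
  if (!any(keep)) return(c(max = 0, mean = 0))
  s <- score_lookup(ppi, a[keep], b[keep])
  c(max = max(s), mean = mean(s))
}

# Per-drug within-target-set summaries: max and mean of scores over the
# C(|T|, 2) unordered pairs; a singleton set has no pairs and scores (0, 0).
within_stats <- function(targets, ppi) {
  targets <- unique(as.character(targets))
  k <- length(targets)
  if (k < 2) return(c(max = 0, mean = 0))
  i <- sequence(1:(k - 1))
  j <- rep.int(2:k, 1:(k - 1))
  s <- score_lookup(ppi, targets[i], targets[j])
  c(max = max(s), mean = mean(s))
}

#' Within-target-group interaction features of a drug pair
#'
#' For each drug, `v1` = max and `v2` = mean of interaction scores over
#' unordered pairs within its target set (singleton sets score 0). Returns
#' the order-free combination `(v1_a + v1_b, v2_a + v2_b, |v1_a - v1_b|,
#' |v2_a - v2_b|)`.
#'
#' @param T1,T2 Non-empty character vectors of target ids.
#' @param ppi Protein [score_table()].
#' @return Named numeric vector of length 4.
#' @export
within_group_features <- function(T1, T2, ppi) {
  w1 <- within_stats(T1, ppi)
  w2 <- within_stats(T2, ppi)
  c(sum_max = unname(w1["max"] + w2["max"]),
    sum_mean = unname(w1["mean"] + w2["mean"]),
    absdiff_max = unname(abs(w1["max"] - w2["max"])),
    absdiff_mean = unname(abs(w1["mean"] - w2["mean"])))
}

#' Pathway-enrichment features of a drug pair
#'
#' Concatenates the P per-pathway sums `e1 + e2` and the P absolute
#' differences `|e1 - e2|`, in pathway order. For P = 229 pathways this
#' contributes the 458 enrichment features.
#'
#' @param e1,e2 Numeric vectors of enrichment scores with identical pathway
#'   names in identical order.
#' @return Numeric vector of length `2 * length(e1)`.
#' @export
pathway_features <- function(e1, e2) {
  if (length(e1) != length(e2) ||
      !identical(names(e1), names(e2))) {
    stop("enrichment profiles disagree in pathway order")
  }
  c(e1 + e2, abs(e1 - e2))
}

#' Build the labelled feature matrix for a set of drug pairs
#'
#' One row per pair, positives first then negatives, each block sorted by
#' canonical pair id. Columns follow [pair_feature_names()]. Per-drug
#' within-group statistics are computed once per drug and reused.
#'
#' @param labels A [combination_labels()].
#' @param drugs Named list: drug id -> target id vector.
#' @param chem Chemical [score_table()].
#' @param ppi Protein [score_table()].
#' @param profiles Enrichment matrix from [profile_all()] (drugs x pathways).
#' @return List of class `pair_features`: `features` (numeric matrix),
#'   `labels` (integer 1/0), `pairs` (data.table drug1, drug2),
#'   `feature_names`.
#' @export
build_matrix <- function(labels, drugs, chem, ppi, profiles) {
  stopifnot(inherits(labels, "combination_labels"))
  pairs <- rbind(labels$positives, labels$negatives)
  y <- c(rep(1L, nrow(labels$positives)), rep(0L, nrow(labels$negatives)))
  missing <- setdiff(unique(c(pairs$drug1, pairs$drug2)), names(drugs))
  if (length(missing) > 0) {
    stop("pairs reference drugs without target data: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (!all(unique(c(pairs$drug1, pairs$drug2)) %in% rownames(profiles))) {
    stop("pairs reference drugs absent from the enrichment profiles")
  }
  P <- ncol(profiles)
  fnames <- pair_feature_names(colnames(profiles))

  within <- vapply(drugs, within_stats, numeric(2), ppi = ppi)  # 2 x n_drugs

  n <- nrow(pairs)
  X <- matrix(0, nrow = n, ncol = length(fnames),
              dimnames = list(NULL, fnames))
  X[, "chem"] <- chemical_feature(pairs$drug1, pairs$drug2, chem)
  for (r in seq_len(n)) {
    d1 <- pairs$drug1[r]; d2 <- pairs$drug2[r]
    X[r, 2:3] <- cross_group_features(drugs[[d1]], drugs[[d2]], ppi)
    w1 <- within[, d1]; w2 <- within[, d2]
    X[r, 4:7] <- c(w1[1] + w2[1], w1[2] + w2[2],
                   abs(w1[1] - w2[1]), abs(w1[2] - w2[2]))
  }
  E1 <- profiles[pairs$drug1, , drop = FALSE]
  E2 <- profiles[pairs$drug2, , drop = FALSE]
  X[, 7L + seq_len(P)] <- E1 + E2
  X[, 7L + P + seq_len(P)] <- abs(E1 - E2)

  structure(list(features = X, labels = y, pairs = pairs,
                 feature_names = fnames),
            class = "pair_features")
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("<pair_features %d pairs x %d features (%d positive)>\n",
              nrow(x$features), ncol(x$features), sum(x$labels)))
  invisible(x)
}

#' Write a feature matrix as TSV (drug1, drug2, label, then features)
#' @param pf A `pair_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(pf, path) {
  stopifnot(inherits(pf, "pair_features"))
  dt <- data.table::data.table(drug1 = pf$pairs$drug1,
                               drug2 = pf$pairs$drug2,
                               label = pf$labels)
  fx <- data.table::as.data.table(pf$features)
  data.table::fwrite(cbind(dt, fx), path, sep = "\t")
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path.
#' @return A `pair_features` object.
#' @export
read_feature_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  X <- as.matrix(dt[, -(1:3)])
  storage.mode(X) <- "double"
  structure(list(features = X, labels = as.integer(dt$label),
                 pairs = dt[, .(drug1, drug2)],
                 feature_names = colnames(X)),
            class = "pair_features")
}
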