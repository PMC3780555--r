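# Minimum-redundancy maximum-relevance feature ranking on the labelled
# feature matrix. Continuous features are discretized into three states at
# mean +/- one (sample) standard deviation — the default of the classic mRMR
# program — and mutual information is the plug-in estimate on the empirical
# joint distribution, in bits.

#' Three-state discretization at mean plus/minus one standard deviation
#'
#' Values below `mean - sd` map to -1, above `mean + sd` to +1, the rest
#' (inclusive boundaries) to 0. A constant column (sd = 0) maps entirely
#' to 0. The sd uses the n-1 denominator.
#'
#' @param column Finite numeric vector.
#' @return Integer vector in \{-1, 0, 1\} of the same length.
#' @export
discretize <- function(column) {
  stopifnot(is.numeric(column), all(is.finite(column)))
  out <- integer(length(column))
  if (length(column) < 2) return(out)
  s <- stats::sd(column)
  if (!is.finite(s) || s == 0) return(out)
  mu <- mean(column)
  out[column < mu - s] <- -1L
  out[column > mu + s] <- 1L
  out
}

#' Plug-in mutual information of two discrete vectors
#'
#' Empirical mutual information in bits: `MI(x, x) = H(x)`; MI with a
#' constant vector is 0; MI is symmetric and non-negative.
#'
#' @param x,y Vectors of equal length (coerced to factors of their observed
#'   values).
#' @param base Logarithm base (default 2, bits).
#' @return Non-negative number.
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0) stop("vectors must be non-empty")
  xi <- as.integer(factor(x)) - 1L
  yi <- as.integer(factor(y)) - 1L
  mi_codes(xi, max(xi) + 1L, yi, max(yi) + 1L) / log2(base)
}

# Fast MI (bits) on integer codes 0..(nx-1), 0..(ny-1).
mi_codes <- function(xi, nx, yi, ny) {
  n <- length(xi)
  joint <- tabulate(xi * ny + yi + 1L, nbins = nx * ny)
  px <- tabulate(xi + 1L, nbins = nx) / n
  py <- tabulate(yi + 1L, nbins = ny) / n
  pj <- joint / n
  # expected joint under independence, aligned with pj's x-major layout
  pe <- rep(px, each = ny) * rep.int(py, nx)
  nzero <- pj > 0
  # mathematically >= 0; clamp the last-ulp negatives from summation error
  max(0, sum(pj[nzero] * log2(pj[nzero] / pe[nzero])))
}

#' Rank features by MaxRel and mRMR
#'
#' Discretizes every feature column, computes each feature's relevance
#' (mutual information with the class label, on the full dataset), and
#' produces two orderings of the complete feature set:
#'
#' * **MaxRel**: features sorted by non-increasing relevance.
#' * **mRMR**: greedy; the first feature is the relevance argmax, and each
#'   subsequent pick maximizes `relevance(f) - mean(MI(f, s))` over selected
#'   `s` (the MID objective, the classic program's default) or
#'   `relevance(f) / mean(MI(f, s))` (MIQ).
#'
#' Ties everywhere break toward the lower original column index, so the
#' output is fully deterministic.
#'
#' @param features Numeric matrix (rows = pairs) with column names, or a
#'   `pair_features` object.
#' @param labels Binary vector with both classes present (ignored when
#'   `features` is a `pair_features` object).
#' @param variant `"mid"` (default) or `"miq"`.
#' @return Object of class `ranked_features`: `maxrel` and `mrmr` (character
#'   vectors, permutations of the feature names), `relevance` (named numeric),
#'   and `selection_trace` (data.table: step, feature, relevance, redundancy,
#'   objective).
#' @export
rank_features <- function(features, labels = NULL,
                          variant = c("mid", "miq")) {
  variant <- match.arg(variant)
  if (inherits(features, "pair_features")) {
    labels <- features$labels
    features <- features$features
  }
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  if (ncol(features) < 2) stop("need at least 2 features to rank")
  if (length(labels) != nrow(features)) stop("labels/matrix length mismatch")
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; relevance is undefined")
  }
  M <- ncol(features)
  fnames <- colnames(features)
  # integer codes 0..2 per column; label codes 0/1
  D <- matrix(0L, nrow = nrow(features), ncol = M)
  for (j in seq_len(M)) D[, j] <- discretize(features[, j]) + 1L
  yi <- as.integer(factor(labels)) - 1L
  ny <- max(yi) + 1L

  rel <- vapply(seq_len(M), function(j) mi_codes(D[, j], 3L, yi, ny),
                numeric(1))
  names(rel) <- fnames
  maxrel_idx <- order(-rel, seq_len(M))

  selected <- integer(M)
  redsum <- numeric(M)       # cumulative MI with selected features
  remaining <- rep(TRUE, M)
  trace <- data.table::data.table(step = seq_len(M), feature = "",
                                  relevance = 0, redundancy = 0,
                                  objective = 0)
  first <- maxrel_idx[1]
  selected[1] <- first
  remaining[first] <- FALSE
  data.table::set(trace, 1L, c("feature", "relevance", "redundancy",
                               "objective"),
                  list(fnames[first], rel[first], 0, rel[first]))
  for (step in seq_len(M - 1)) {
    last <- selected[step]
    cand <- which(remaining)
    for (j in cand) {
      redsum[j] <- redsum[j] + mi_codes(D[, j], 3L, D[, last], 3L)
    }
    meanred <- redsum[cand] / step
    obj <- if (variant == "mid") {
      rel[cand] - meanred
    } else {
      rel[cand] / pmax(meanred, 1e-12)
    }
    pick <- cand[order(-obj, cand)[1]]
    selected[step + 1] <- pick
    remaining[pick] <- FALSE
    data.table::set(trace, step + 1L,
                    c("feature", "relevance", "redundancy", "objective"),
                    list(fnames[pick], unname(rel[pick]),
                         redsum[pick] / step,
                         unname(obj[match(pick, cand)])))
  }

  structure(list(maxrel = fnames[maxrel_idx], mrmr = fnames[selected],
                 relevance = rel, selection_trace = trace,
                 variant = variant),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features %d features, variant=%s>\n",
              length(x$mrmr), x$variant))
  cat("top mRMR:", paste(utils::head(x$mrmr, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Write MaxRel and mRMR ranked lists as TSVs
#'
#' Emits `<prefix>_maxrel.tsv` and `<prefix>_mrmr.tsv`, each with columns
#' rank, feature, relevance (and objective for the mRMR list).
#'
#' @param ranked A `ranked_features` object.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_ranked_lists <- function(ranked, prefix) {
  stopifnot(inherits(ranked, "ranked_features"))
  p1 <- paste0(prefix, "_maxrel.tsv")
  p2 <- paste0(prefix, "_mrmr.tsv")
  data.table::fwrite(data.table::data.table(
    rank = seq_along(ranked$maxrel), feature = ranked$maxrel,
    relevance = unname(ranked$relevance[ranked$maxrel])), p1, sep = "\t")
  tr <- data.table::copy(ranked$selection_trace)
  data.table::setnames(tr, "step", "rank")
  data.table::fwrite(tr, p2, sep = "\t")
  invisible(c(p1, p2))
}
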