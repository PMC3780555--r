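# Generator for STITCH/STRING/GMT-shaped synthetic inputs with a
# configurable planted signal. The signal is injected at the data layer
# (scores, network edges, pathway membership) and never into feature values,
# so the enrichment and feature-building code paths are exercised end to end.
#
# Planted signal channels:
#   * chem_shift       — positive pairs' chemical score is raised by this
#                        amount (clamped at 999), making the "chem" feature
#                        informative;
#   * cross_ppi_boost  — each absent cross-target protein pair of a positive
#                        pair gains an interaction edge with this
#                        probability, driving ppi_cross_max / ppi_cross_mean;
#   * n_signal_pathways — for this many designated pathways, the two drugs of
#                        a positive pair receive the same "affinity" (number
#                        of pathway genes wired to their targets), so their
#                        enrichment scores are correlated within positive
#                        pairs: the absdiff features shrink and the sum
#                        features rise for positives.

#' Synthetic-benchmark configuration
#'
#' Defaults reproduce the benchmark's shape: 169 drugs, 121 positive pairs,
#' 5 random negatives per positive, 229 pathways over a 20,000-gene universe,
#' target sets of 1-8 proteins — with zero planted signal (the null world).
#' Background interaction tables are sparse symmetric integer score tables on
#' the 150-999 range.
#'
#' @param n_drugs,n_proteins,universe_size,n_pathways Dimension counts.
#' @param targets_min,targets_max Per-drug target-set size range.
#' @param chem_density,ppi_density Bernoulli edge probabilities for the
#'   background score tables.
#' @param pathway_size_min,pathway_size_max Pathway gene-set size range.
#' @param n_positives,negative_ratio Labelled-pair counts.
#' @param chem_shift,cross_ppi_boost,n_signal_pathways Planted signal (see
#'   details above); all zero by default.
#' @param seed Master seed; the full generation is deterministic given it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 169, n_proteins = 2000,
                         universe_size = 20000, n_pathways = 229,
                         targets_min = 1, targets_max = 8,
                         chem_density = 0.05, ppi_density = 0.002,
                         pathway_size_min = 10, pathway_size_max = 60,
                         n_positives = 121, negative_ratio = 5,
                         chem_shift = 0, cross_ppi_boost = 0,
                         n_signal_pathways = 0, seed = 1) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_proteins = as.integer(n_proteins),
              universe_size = as.integer(universe_size),
              n_pathways = as.integer(n_pathways),
              targets_min = as.integer(targets_min),
              targets_max = as.integer(targets_max),
              chem_density = chem_density, ppi_density = ppi_density,
              pathway_size_min = as.integer(pathway_size_min),
              pathway_size_max = as.integer(pathway_size_max),
              n_positives = as.integer(n_positives),
              negative_ratio = as.integer(negative_ratio),
              chem_shift = chem_shift, cross_ppi_boost = cross_ppi_boost,
              n_signal_pathways = as.integer(n_signal_pathways),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_drugs >= 2, n_proteins >= targets_max, n_pathways >= 1,
              targets_min >= 1, targets_max >= targets_min,
              chem_density >= 0, chem_density <= 1,
              ppi_density >= 0, ppi_density <= 1,
              pathway_size_min >= 1, pathway_size_max >= pathway_size_min,
              pathway_size_max <= n_proteins,
              pathway_size_max <= universe_size,
              n_positives >= 1, negative_ratio >= 1,
              n_signal_pathways <= n_pathways,
              chem_shift >= 0, cross_ppi_boost >= 0, cross_ppi_boost <= 1)
    if (n_positives * (1 + negative_ratio) > n_unordered_pairs(n_drugs)) {
      stop("infeasible config: not enough drug pairs for the requested ",
           "positives and negatives")
    }
  })
  structure(cfg, class = "synth_config")
}

# Bernoulli(density) background edges over all unordered pairs of `ids`,
# scored with uniform integers in score_range. Draws from the current RNG.
sample_background_edges <- function(ids, density, score_range = c(150L, 999L)) {
  n <- length(ids)
  n_all <- n_unordered_pairs(n)
  ne <- stats::rbinom(1, n_all, density)
  if (ne == 0) {
    return(data.table::data.table(id1 = character(), id2 = character(),
                                  score = numeric()))
  }
  pick <- sample(n_all, ne)
  ij <- pair_from_index(pick, n)
  data.table::data.table(
    id1 = ids[ij$i], id2 = ids[ij$j],
    score = as.numeric(sample(score_range[1]:score_range[2], ne,
                              replace = TRUE)))
}

# Decode linear indices (ordered by j, then i < j) of the unordered-pair
# enumeration over n items into (i, j) index pairs.
pair_from_index <- function(idx, n) {
  j <- rep.int(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  list(i = i[idx], j = j[idx])
}

#' Generate a synthetic benchmark
#'
#' Produces every input the pipeline consumes: a drug-target table, chemical
#' and protein score tables, a pathway annotation, and a labelled pair set
#' whose negatives are drawn by [sample_negatives()]. Fully deterministic for
#' a fixed `config$seed`; the caller's RNG state is untouched.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_data`: `drugs` (named list of target sets),
#'   `chem`, `ppi` ([score_table()]s), `annotation`
#'   ([pathway_annotation()]), `labels` ([combination_labels()]),
#'   `signal_features` (character vector naming the features the planted
#'   signal should make informative), and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    drug_ids <- sprintf("D%04d", seq_len(config$n_drugs))
    prot_ids <- sprintf("P%05d", seq_len(config$n_proteins))
    pw_ids <- sprintf("PW%04d", seq_len(config$n_pathways))

    # target sets: uniform size in [targets_min, targets_max]
    sizes <- sample(config$targets_min:config$targets_max, config$n_drugs,
                    replace = TRUE)
    drugs <- lapply(sizes, function(k) sort(sample(prot_ids, k)))
    names(drugs) <- drug_ids

    chem_edges <- sample_background_edges(drug_ids, config$chem_density)
    ppi_edges <- sample_background_edges(prot_ids, config$ppi_density)

    # pathway gene sets over the protein pool; the universe is larger (most
    # of the organism's genes are neither targets nor their neighbours)
    pw_sizes <- sample(config$pathway_size_min:config$pathway_size_max,
                       config$n_pathways, replace = TRUE)
    pathways <- lapply(pw_sizes, function(k) sort(sample(prot_ids, k)))
    names(pathways) <- pw_ids

    # labelled pairs
    all_idx <- sample(n_unordered_pairs(config$n_drugs), config$n_positives)
    ij <- pair_from_index(all_idx, config$n_drugs)
    positives <- data.table::data.table(drug1 = drug_ids[ij$i],
                                        drug2 = drug_ids[ij$j])
    neg_seed <- sample.int(2147483646, 1)

    # --- planted signal -------------------------------------------------
    if (config$chem_shift > 0) {
      base <- score_table(chem_edges$id1, chem_edges$id2, chem_edges$score,
                          kind = "chemical")
      q <- score_lookup(base, positives$drug1, positives$drug2)
      chem_edges <- rbind(chem_edges, data.table::data.table(
        id1 = positives$drug1, id2 = positives$drug2,
        score = pmin(999, q + config$chem_shift)))
    }

    if (config$cross_ppi_boost > 0) {
      extra <- vector("list", nrow(positives))
      for (r in seq_len(nrow(positives))) {
        t1 <- drugs[[positives$drug1[r]]]
        t2 <- drugs[[positives$drug2[r]]]
        a <- rep(t1, times = length(t2))
        b <- rep(t2, each = length(t1))
        keep <- a != b & stats::runif(length(a)) < config$cross_ppi_boost
        if (any(keep)) {
          extra[[r]] <- data.table::data.table(
            id1 = a[keep], id2 = b[keep],
            score = as.numeric(sample(150:999, sum(keep), replace = TRUE)))
        }
      }
      ppi_edges <- rbind(ppi_edges, data.table::rbindlist(extra))
    }

    signal_pathways <- character(0)
    if (config$n_signal_pathways > 0) {
      signal_pathways <- sort(pw_ids)[seq_len(config$n_signal_pathways)]
      # per-(drug, pathway) affinity: number of pathway genes wired to the
      # drug's targets. Enrichment is a per-drug quantity, so a pair-level
      # correlation can only be planted through shared drug-level values:
      # every drug in one connected component of the positive-pair graph
      # gets the component's affinity (positive pairs then agree exactly),
      # while unpaired drugs draw independently. Negative pairs agree only
      # when both drugs happen to sit in the same component.
      comp <- seq_len(config$n_drugs)        # union-find over drug indices
      names(comp) <- drug_ids
      find <- function(i) {
        while (comp[i] != i) {
          comp[i] <<- comp[comp[i]]
          i <- comp[i]
        }
        i
      }
      for (r in seq_len(nrow(positives))) {
        a <- find(match(positives$drug1[r], drug_ids))
        b <- find(match(positives$drug2[r], drug_ids))
        if (a != b) comp[b] <- a
      }
      root <- vapply(seq_len(config$n_drugs), find, integer(1))
      affinity <- matrix(NA_integer_, nrow = config$n_drugs,
                         ncol = length(signal_pathways),
                         dimnames = list(drug_ids, signal_pathways))
      # Widely spaced affinity levels: the hypergeometric score also moves
      # with each drug's expanded-set size n, so adjacent levels must differ
      # by more than that nuisance variation for the planted correlation to
      # be recoverable.
      for (pj in signal_pathways) {
        comp_level <- sample(c(0L, 4L, 8L, 12L), config$n_drugs,
                             replace = TRUE)
        affinity[, pj] <- comp_level[root]
      }
      wires <- list()
      for (pj in signal_pathways) {
        genes <- pathways[[pj]]
        for (d in drug_ids) {
          k <- min(affinity[d, pj], length(genes))
          if (k > 0) {
            g <- sample(genes, k)
            t <- sample(drugs[[d]], 1)
            keep <- g != t
            if (any(keep)) {
              wires[[length(wires) + 1]] <- data.table::data.table(
                id1 = t, id2 = g[keep],
                score = as.numeric(sample(400:999, sum(keep),
                                          replace = TRUE)))
            }
          }
        }
      }
      if (length(wires) > 0) {
        ppi_edges <- rbind(ppi_edges, data.table::rbindlist(wires))
      }
    }
    # ---------------------------------------------------------------------

    chem <- score_table(chem_edges$id1, chem_edges$id2, chem_edges$score,
                        kind = "chemical")
    ppi <- score_table(ppi_edges$id1, ppi_edges$id2, ppi_edges$score,
                       kind = "protein")
    annotation <- pathway_annotation(pathways, config$universe_size)
    labels <- sample_negatives(drug_ids, positives,
                               config$negative_ratio, neg_seed)

    signal_features <- character(0)
    if (config$chem_shift > 0) signal_features <- "chem"
    if (config$cross_ppi_boost > 0) {
      signal_features <- c(signal_features, "ppi_cross_max",
                           "ppi_cross_mean")
    }
    if (length(signal_pathways) > 0) {
      signal_features <- c(signal_features,
                           paste0("absdiff:", signal_pathways))
    }

    structure(list(drugs = drugs, chem = chem, ppi = ppi,
                   annotation = annotation, labels = labels,
                   signal_features = signal_features, config = config),
              class = "synth_data")
  })
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf(
    "<synth_data drugs=%d chem pairs=%d ppi pairs=%d pathways=%d pos=%d neg=%d>\n",
    length(x$drugs), n_pairs(x$chem), n_pairs(x$ppi),
    length(x$annotation$pathways), nrow(x$labels$positives),
    nrow(x$labels$negatives)))
  invisible(x)
}

#' Write a synthetic benchmark to disk in the loaders' dialects
#'
#' Emits `drug_targets.tsv`, `chem_links.tsv` (chemical1, chemical2,
#' combined_score), `ppi_links.tsv` (protein1, protein2, combined_score),
#' `pathways.gmt`, `positives.tsv` and `negatives.tsv` under `dir`. All five
#' round-trip losslessly through the corresponding loaders.
#'
#' @param data A `synth_data` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
synth_write <- function(data, dir) {
  stopifnot(inherits(data, "synth_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(targets = file.path(dir, "drug_targets.tsv"),
             chem = file.path(dir, "chem_links.tsv"),
             ppi = file.path(dir, "ppi_links.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             positives = file.path(dir, "positives.tsv"),
             negatives = file.path(dir, "negatives.tsv"))
  write_drug_targets(data$drugs, paths["targets"])
  write_score_tsv <- function(tbl, path, id_names) {
    dt <- tbl$entries[id1 < id2]
    data.table::setorder(dt, id1, id2)
    data.table::setnames(dt, c("id1", "id2", "score"),
                         c(id_names, "combined_score"))
    data.table::fwrite(dt, path, sep = "\t")
  }
  write_score_tsv(data$chem, paths["chem"], c("chemical1", "chemical2"))
  write_score_tsv(data$ppi, paths["ppi"], c("protein1", "protein2"))
  write_pathways(data$annotation, paths["pathways"])
  data.table::fwrite(data$labels$positives, paths["positives"], sep = "\t")
  data.table::fwrite(data$labels$negatives, paths["negatives"], sep = "\t")
  invisible(paths)
}

#' Read a benchmark written by [synth_write()] through the standard loaders
#'
#' @param dir Directory holding the six files.
#' @param universe_size Gene-universe size N (not stored in the GMT).
#' @return List with `drugs`, `chem`, `ppi`, `annotation`, `labels`.
#' @export
synth_read <- function(dir, universe_size) {
  drugs <- load_drug_targets(file.path(dir, "drug_targets.tsv"))
  chem <- load_score_table(file.path(dir, "chem_links.tsv"),
                           kind = "chemical")
  ppi <- load_score_table(file.path(dir, "ppi_links.tsv"), kind = "protein")
  annotation <- load_pathways(file.path(dir, "pathways.gmt"), universe_size)
  labels <- combination_labels(
    load_pair_list(file.path(dir, "positives.tsv")),
    load_pair_list(file.path(dir, "negatives.tsv")),
    names(drugs))
  list(drugs = drugs, chem = chem, ppi = ppi, annotation = annotation,
       labels = labels)
}
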