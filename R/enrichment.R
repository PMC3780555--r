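# Per-drug pathway enrichment: a drug's target set is expanded by its direct
# neighbours in the protein-interaction network, and the expanded gene set is
# scored against each pathway with the upper tail of the hypergeometric
# distribution; the score is -log10 of that tail probability.

# Scores saturate where the tail probability underflows double precision.
.SCORE_CAP <- 300

#' Expand a target set by direct network neighbours
#'
#' Returns the union of a drug's targets and every protein whose interaction
#' confidence score with at least one target exceeds `threshold`. With the
#' default `threshold = 0`, any stored (positive) score counts as
#' "interactive".
#'
#' @param targets Non-empty character vector of target protein ids.
#' @param ppi A protein [score_table()].
#' @param threshold Numeric; neighbour scores must exceed this.
#' @return Sorted character vector: targets plus one-hop neighbours.
#' @export
expand_targets <- function(targets, ppi, threshold = 0) {
  targets <- unique(as.character(targets))
  if (length(targets) == 0) stop("target set is empty")
  if (!is.numeric(threshold) || length(threshold) != 1) {
    stop("neighbor threshold must be a single number")
  }
  sort(unique(c(targets, score_neighbors(ppi, targets, threshold))))
}

#' Hypergeometric enrichment score from counts
#'
#' Computes `-log10 P[X >= m]` where `X ~ Hypergeometric(N, M, n)`: from an
#' urn of `N` genes of which `M` belong to the pathway, `n` are drawn (the
#' drug's expanded gene set) and `m` of them hit the pathway. `m = 0` scores
#' exactly 0 (the tail probability is 1). The score is capped at 300, the
#' saturation point of double-precision tail probabilities.
#'
#' Implemented via the survival function at `m - 1` (numerically stable); the
#' naive tail summation serves as the test oracle, not the implementation.
#'
#' @param N Universe size (genes in the organism).
#' @param M Pathway size, `0 < M <= N`.
#' @param n Gene-set size, `0 < n <= N`.
#' @param m Overlap count, `0 <= m <= min(M, n)`.
#' @return Non-negative number, at most 300.
#' @export
#' @examples
#' enrichment_score_counts(20, 5, 4, 2)  # -log10(1205/4845)
enrichment_score_counts <- function(N, M, n, m) {
  stopifnot(length(N) == 1, length(M) == 1, length(n) == 1, length(m) == 1)
  if (M <= 0 || M > N) stop("pathway size M must satisfy 0 < M <= N")
  if (n <= 0 || n > N) stop("gene-set size n must satisfy 0 < n <= N")
  if (m < 0 || m > min(M, n)) stop("overlap m must satisfy 0 <= m <= min(M, n)")
  if (m == 0) return(0)
  p <- stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  p <- min(max(p, 0), 1)  # clamp accumulation error
  if (p == 0) return(.SCORE_CAP)
  min(-log10(p), .SCORE_CAP)
}

#' Hypergeometric enrichment score of a gene set against a pathway
#'
#' Set-level wrapper around [enrichment_score_counts()]: `m` is the overlap
#' between `gene_set` and `pathway_genes`, `n` the gene-set size, `M` the
#' pathway size. When `universe_genes` is supplied both sets are intersected
#' with it first; otherwise `universe_size` is trusted as given and only the
#' counts enter the model.
#'
#' @param gene_set Character vector (a drug's expanded target set).
#' @param pathway_genes Character vector of the pathway's genes.
#' @param universe_size The universe size N.
#' @param universe_genes Optional universe membership vector.
#' @return Non-negative number, at most 300.
#' @export
enrichment_score <- function(gene_set, pathway_genes, universe_size,
                             universe_genes = NULL) {
  gene_set <- unique(as.character(gene_set))
  pathway_genes <- unique(as.character(pathway_genes))
  if (!is.null(universe_genes)) {
    gene_set <- intersect(gene_set, universe_genes)
    pathway_genes <- intersect(pathway_genes, universe_genes)
  }
  enrichment_score_counts(universe_size, length(pathway_genes),
                          length(gene_set),
                          length(intersect(gene_set, pathway_genes)))
}

#' Enrichment profiles for a set of drugs
#'
#' One row per drug, one column per pathway (in the annotation's fixed,
#' id-sorted order): the enrichment score of the drug's network-expanded
#' target set against each pathway. A pure function of its inputs.
#'
#' @param drugs Named list: drug id -> character vector of target ids.
#' @param ppi Protein [score_table()] used for one-hop expansion.
#' @param annotation A [pathway_annotation()].
#' @param neighbor_threshold Passed to [expand_targets()].
#' @return Numeric matrix, `length(drugs)` x `P`, with drug ids as rownames
#'   and pathway ids as colnames.
#' @export
profile_all <- function(drugs, ppi, annotation, neighbor_threshold = 0) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  if (is.null(names(drugs)) || any(!nzchar(names(drugs)))) {
    stop("drugs must be a named list")
  }
  if (any(lengths(drugs) == 0)) {
    bad <- names(drugs)[lengths(drugs) == 0][1]
    stop("drug without target information: ", bad)
  }
  pw <- annotation$pathways
  N <- annotation$universe_size
  ug <- annotation$universe_genes
  pw_use <- if (is.null(ug)) pw else lapply(pw, intersect, ug)
  M <- lengths(pw_use)
  # gene -> pathway index lookup for fast overlap counting
  gene2pw <- data.table::data.table(
    gene = unlist(pw_use, use.names = FALSE),
    pw = rep(seq_along(pw_use), lengths(pw_use)))
  data.table::setkey(gene2pw, gene)
  P <- length(pw)
  out <- matrix(0, nrow = length(drugs), ncol = P,
                dimnames = list(names(drugs), names(pw)))
  for (d in names(drugs)) {
    gs <- expand_targets(drugs[[d]], ppi, neighbor_threshold)
    if (!is.null(ug)) gs <- intersect(gs, ug)
    n <- length(gs)
    if (n == 0 || n > N) {
      stop(sprintf("gene set for drug %s has size %d outside (0, N]", d, n))
    }
    hits <- gene2pw[data.table::data.table(gene = gs), on = "gene",
                    nomatch = NULL]
    m <- tabulate(hits$pw, nbins = P)
    nz <- which(m > 0)
    if (length(nz) > 0) {
      p <- stats::phyper(m[nz] - 1, M[nz], N - M[nz], n, lower.tail = FALSE)
      p <- pmin(pmax(p, 0), 1)
      s <- ifelse(p == 0, .SCORE_CAP, pmin(-log10(p), .SCORE_CAP))
      out[d, nz] <- s
    }
  }
  out
}

#' Write enrichment profiles as TSV (rows = drugs, columns = pathways)
#' @param profiles Matrix from [profile_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  dt <- data.table::data.table(drug_id = rownames(profiles))
  # %.17g: shortest-exact for doubles, so persisted profiles round-trip
  # bit-identically and re-running a later stage from disk reproduces the
  # in-memory feature matrix byte for byte
  for (j in colnames(profiles)) {
    dt[[j]] <- sprintf("%.17g", profiles[, j])
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read enrichment profiles written by [write_profiles()]
#' @param path TSV path.
#' @return Numeric matrix with drug ids as rownames.
#' @export
read_profiles <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L))
  m <- as.matrix(dt[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- dt[[1]]
  m
}
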