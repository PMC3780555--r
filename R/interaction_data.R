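# Loading and serving drug targets, interaction confidence scores and
# pathway annotations. Scores live on their raw database scale (e.g. 0-999
# for STITCH/STRING dumps); a pair absent from a table scores exactly 0.

# Separator used to build canonical unordered-pair keys. Ids are opaque
# strings; the unit separator never occurs in tab-separated input fields.
.PAIR_SEP <- "\x1f"

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = .PAIR_SEP)
}

#' Number of unordered pairs over n items
#'
#' The candidate-combination count for a drug universe: `n * (n - 1) / 2`.
#' For the 169-drug benchmark this is 14,196.
#'
#' @param n Non-negative integer.
#' @return A number.
#' @export
#' @examples
#' n_unordered_pairs(169)
n_unordered_pairs <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0, n == floor(n))
  n * (n - 1) / 2
}

#' Construct a symmetric confidence-score table
#'
#' A `score_table` maps unordered id pairs to positive confidence scores on
#' their raw database scale. Lookups of absent pairs (and of self pairs,
#' which are never stored) return exactly 0. Duplicate input rows for the
#' same unordered pair collapse to their maximum score; rows with score <= 0
#' are dropped.
#'
#' @param id1,id2 Character vectors of interactor ids (row-parallel).
#' @param score Numeric vector of confidence scores.
#' @param kind `"chemical"` or `"protein"`.
#' @return An object of class `score_table`.
#' @export
score_table <- function(id1 = character(), id2 = character(),
                        score = numeric(), kind = c("chemical", "protein")) {
  kind <- match.arg(kind)
  stopifnot(length(id1) == length(id2), length(id1) == length(score))
  dt <- data.table::data.table(id1 = as.character(id1),
                               id2 = as.character(id2),
                               score = as.numeric(score))
  dt <- dt[!is.na(score) & score > 0 & !is.na(id1) & !is.na(id2) &
             id1 != id2]
  if (nrow(dt) > 0) {
    a <- pmin(dt$id1, dt$id2)
    b <- pmax(dt$id1, dt$id2)
    dt <- data.table::data.table(id1 = a, id2 = b, score = dt$score)
    dt <- dt[, .(score = max(score)), by = .(id1, id2)]
    # store both orientations so neighbour queries are a single keyed join
    dt <- rbind(dt, data.table::data.table(id1 = dt$id2, id2 = dt$id1,
                                           score = dt$score))
  }
  data.table::setkey(dt, id1, id2)
  structure(list(entries = dt, kind = kind), class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table kind=%s pairs=%d>\n", x$kind, n_pairs(x)))
  invisible(x)
}

#' Number of distinct unordered pairs stored in a score table
#' @param table A `score_table`.
#' @return An integer.
#' @export
n_pairs <- function(table) {
  stopifnot(inherits(table, "score_table"))
  nrow(table$entries) / 2L
}

#' Load a confidence-score table from a STITCH/STRING-style TSV
#'
#' Reads a tab-separated file (plain or gzip) with a header, keeps the two
#' leading id columns plus `score_column`, drops rows with non-positive or
#' unparseable scores (counted and reported via [message()]), collapses
#' duplicate unordered pairs to their maximum score, and never stores self
#' pairs.
#'
#' @param path File path.
#' @param kind `"chemical"` or `"protein"`.
#' @param score_column Name of the score column (default `"combined_score"`).
#' @param id_columns Names (or 2 indices) of the interactor id columns;
#'   defaults to the first two columns.
#' @return A [score_table()].
#' @export
load_score_table <- function(path, kind = c("chemical", "protein"),
                             score_column = "combined_score",
                             id_columns = c(1L, 2L)) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = id_columns))
  if (!score_column %in% names(dt)) {
    stop(sprintf("score column '%s' not found in %s (columns: %s)",
                 score_column, path, paste(names(dt), collapse = ", ")))
  }
  ids <- if (is.numeric(id_columns)) names(dt)[id_columns] else id_columns
  if (any(is.na(ids)) || !all(ids %in% names(dt))) {
    stop("id columns not found in ", path)
  }
  sc <- suppressWarnings(as.numeric(dt[[score_column]]))
  bad <- is.na(sc) | is.na(dt[[ids[1]]]) | is.na(dt[[ids[2]]]) |
    dt[[ids[1]]] == "" | dt[[ids[2]]] == ""
  if (any(bad)) {
    message(sprintf("load_score_table: skipped %d malformed row(s) in %s",
                    sum(bad), path))
  }
  score_table(dt[[ids[1]]][!bad], dt[[ids[2]]][!bad], sc[!bad], kind = kind)
}

#' Look up confidence scores for id pairs
#'
#' Vectorised symmetric lookup: `score_lookup(t, a, b)` equals
#' `score_lookup(t, b, a)`; absent pairs and self pairs return 0.
#'
#' @param table A `score_table`.
#' @param a,b Character vectors of ids (recycled to a common length).
#' @return Numeric vector of scores (0 where absent).
#' @export
score_lookup <- function(table, a, b) {
  stopifnot(inherits(table, "score_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (n == 0) return(numeric(0))
  out <- table$entries[data.table::data.table(id1 = pmin(a, b),
                                              id2 = pmax(a, b)),
                       score, on = c("id1", "id2")]
  out[is.na(out)] <- 0
  out[a == b] <- 0  # self pairs are not defined; 0 by convention
  out
}

#' Direct interaction neighbours of a set of ids
#'
#' Returns every id whose stored confidence score with at least one query id
#' exceeds `threshold`. With the default `threshold = 0` this is the plain
#' "interactive" relation (any stored score counts, since stored scores are
#' positive).
#'
#' @param table A `score_table`.
#' @param ids Character vector of query ids.
#' @param threshold Scores must be strictly greater than this to count.
#' @return Character vector of neighbour ids (may include query ids when
#'   they interact with each other).
#' @export
score_neighbors <- function(table, ids, threshold = 0) {
  stopifnot(inherits(table, "score_table"))
  hits <- table$entries[data.table::data.table(id1 = as.character(ids)),
                        on = "id1", nomatch = NULL]
  unique(hits[score > threshold, id2])
}

#' Load drug target sets from a two-column TSV
#'
#' Expects columns `drug_id` and `protein_id` (header required), one row per
#' drug-target pair. Target sets are unions over rows. A drug with an empty
#' target set cannot occur in this format; empty or missing ids are an error
#' because drugs without target information are excluded from the study.
#'
#' @param path File path.
#' @return Named list: drug id -> character vector of target protein ids.
#' @export
load_drug_targets <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("drug_id", "protein_id") %in% names(dt))) {
    stop("drug-target table must have columns drug_id, protein_id: ", path)
  }
  if (any(is.na(dt$drug_id) | dt$drug_id == "" |
            is.na(dt$protein_id) | dt$protein_id == "")) {
    stop("drug-target table contains empty ids: ", path)
  }
  drugs <- split(dt$protein_id, dt$drug_id)
  drugs <- lapply(drugs, function(x) sort(unique(x)))
  drugs[order(names(drugs))]
}

#' Write drug target sets to the two-column TSV dialect
#' @param drugs Named list: drug id -> character vector of targets.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_targets <- function(drugs, path) {
  stopifnot(is.list(drugs), !is.null(names(drugs)),
            all(lengths(drugs) > 0))
  dt <- data.table::data.table(
    drug_id = rep(names(drugs), lengths(drugs)),
    protein_id = unlist(drugs, use.names = FALSE))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Load pathway gene sets from a GMT file
#'
#' GMT: one pathway per line, tab-separated: id, description, then gene ids.
#' Pathways are returned sorted by id so the feature-column order downstream
#' is reproducible.
#'
#' @param path GMT file path.
#' @param universe_size Total number of genes in the organism (N of the
#'   hypergeometric model). Must be at least the largest pathway size.
#' @return Object of class `pathway_annotation`: list with `pathways` (named
#'   list of character vectors, sorted by id) and `universe_size`.
#' @export
load_pathways <- function(path, universe_size) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  pathway_annotation(sets, universe_size)
}

#' Construct a pathway annotation
#'
#' @param pathways Named list: pathway id -> non-empty character vector of
#'   gene ids.
#' @param universe_size Positive integer, the gene-universe size N.
#' @param universe_genes Optional character vector of universe member ids;
#'   when supplied, gene sets are intersected with it at scoring time.
#' @return Object of class `pathway_annotation` with pathways sorted by id.
#' @export
pathway_annotation <- function(pathways, universe_size,
                               universe_genes = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)),
            length(pathways) >= 1,
            is.numeric(universe_size), length(universe_size) == 1,
            universe_size >= 1)
  if (any(lengths(pathways) == 0)) stop("every pathway gene set must be non-empty")
  if (max(lengths(pathways)) > universe_size) {
    stop("a pathway is larger than the gene universe")
  }
  pathways <- pathways[order(names(pathways))]
  structure(list(pathways = pathways,
                 universe_size = as.integer(universe_size),
                 universe_genes = universe_genes),
            class = "pathway_annotation")
}

#' Write pathway gene sets as GMT
#' @param annotation A `pathway_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(annotation, path) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  lines <- vapply(names(annotation$pathways), function(id) {
    paste(c(id, "na", annotation$pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a labelled set of drug combinations
#'
#' @param positives,negatives Two-column objects (matrix, data.frame) of drug
#'   ids, one unordered pair per row.
#' @param drug_ids Character vector of known drug ids; every pair member must
#'   be present.
#' @return Object of class `combination_labels` with `positives` and
#'   `negatives` as canonical (sorted within pair, lexicographic across
#'   pairs) two-column data.tables.
#' @export
combination_labels <- function(positives, negatives, drug_ids) {
  canon <- function(x, what) {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (ncol(x) < 2) stop(what, " must have two columns")
    a <- as.character(x[[1]]); b <- as.character(x[[2]])
    if (any(a == b)) stop(what, " contains a self pair")
    if (!all(c(a, b) %in% drug_ids)) {
      stop(what, " references drug ids absent from the drug table")
    }
    dt <- data.table::data.table(drug1 = pmin(a, b), drug2 = pmax(a, b))
    if (anyDuplicated(dt)) stop(what, " contains duplicate pairs")
    data.table::setorder(dt, drug1, drug2)
    dt
  }
  pos <- canon(positives, "positives")
  neg <- canon(negatives, "negatives")
  if (nrow(data.table::fintersect(pos, neg)) > 0) {
    stop("positives and negatives overlap")
  }
  structure(list(positives = pos, negatives = neg),
            class = "combination_labels")
}

#' @export
print.combination_labels <- function(x, ...) {
  cat(sprintf("<combination_labels positives=%d negatives=%d>\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

#' Load a two-column pair list (TSV with header drug1, drug2)
#' @param path File path.
#' @return Two-column data.table of drug ids.
#' @export
load_pair_list <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (ncol(dt) < 2) stop("pair list must have two columns: ", path)
  dt[, 1:2]
}

#' Sample random negative drug pairs
#'
#' Draws `ratio * nrow(positives)` distinct unordered pairs uniformly without
#' replacement from all candidate pairs over `drugs` that are not positives.
#' Mirrors the benchmark construction in which 605 random combinations were
#' drawn as negatives for 121 positives over 169 drugs (ratio 5). The draw is
#' deterministic for a fixed seed and does not disturb the caller's RNG
#' state.
#'
#' @param drugs Character vector of drug ids (deduplicated, sorted
#'   internally).
#' @param positives Two-column object of positive pairs.
#' @param ratio Positive integer: negatives per positive.
#' @param seed Integer RNG seed.
#' @return A [combination_labels()] holding the given positives and the
#'   sampled negatives.
#' @export
sample_negatives <- function(drugs, positives, ratio, seed) {
  drugs <- sort(unique(as.character(drugs)))
  n <- length(drugs)
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  n_pos <- nrow(positives)
  n_all <- n_unordered_pairs(n)
  n_need <- ratio * n_pos
  if (n_need > n_all - n_pos) {
    stop(sprintf(
      "cannot sample %d negatives: only %d non-positive pairs available",
      n_need, n_all - n_pos))
  }
  # enumerate all unordered index pairs (i < j)
  j <- rep.int(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  keys <- pair_key(drugs[i], drugs[j])
  pos_keys <- pair_key(as.character(positives[[1]]),
                       as.character(positives[[2]]))
  candidate <- which(!(keys %in% pos_keys))
  picked <- local_seed(seed, sample(candidate, n_need, replace = FALSE))
  combination_labels(
    positives = positives,
    negatives = data.frame(drug1 = drugs[i[picked]],
                           drug2 = drugs[j[picked]],
                           stringsAsFactors = FALSE),
    drug_ids = drugs)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
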