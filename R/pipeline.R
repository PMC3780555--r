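# Orchestration: generate-or-ingest -> enrich -> featurize -> rank -> ifs ->
# report, behind one entry point with a config object (JSON file or R list),
# a fixed artifact layout under the output directory, and a manifest
# recording the config hash, every seed, and per-stage shapes so a rerun with
# the same config reproduces identical outputs.

.PIPELINE_STAGES <- c("synth", "enrich", "featurize", "rank", "ifs", "report")

#' Pipeline run configuration
#'
#' @param outdir Output directory for all artifacts.
#' @param input_dir Directory holding the six input files (the dialect of
#'   [synth_write()]); defaults to `<outdir>/input`, where the `synth` stage
#'   writes them.
#' @param synth A [synth_config()] used by the `synth` stage (ignored when
#'   inputs are supplied externally).
#' @param universe_size Gene-universe size N used when ingesting external
#'   inputs; defaults to the synth config's value.
#' @param neighbor_threshold Interaction-score threshold for target-set
#'   expansion (0 = any stored interaction counts).
#' @param mrmr_variant `"mid"` or `"miq"`.
#' @param folds Cross-validation folds.
#' @param n_trees,m_try Forest size and per-node candidate features (`NULL`
#'   for the `floor(log2 M) + 1` rule).
#' @param k_max Largest IFS prefix; `NULL` means all features.
#' @param cv_seed,forest_seed Seeds for fold partition and forest master.
#' @param stratified Stratify CV folds by class.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(outdir, input_dir = file.path(outdir, "input"),
                            synth = synth_config(),
                            universe_size = synth$universe_size,
                            neighbor_threshold = 0,
                            mrmr_variant = "mid", folds = 5,
                            n_trees = 10, m_try = NULL, k_max = NULL,
                            cv_seed = 1, forest_seed = 1,
                            stratified = FALSE) {
  structure(list(outdir = outdir, input_dir = input_dir, synth = synth,
                 universe_size = as.integer(universe_size),
                 neighbor_threshold = neighbor_threshold,
                 mrmr_variant = mrmr_variant, folds = as.integer(folds),
                 n_trees = as.integer(n_trees),
                 m_try = if (is.null(m_try)) NULL else as.integer(m_try),
                 k_max = if (is.null(k_max)) NULL else as.integer(k_max),
                 cv_seed = as.integer(cv_seed),
                 forest_seed = as.integer(forest_seed),
                 stratified = isTRUE(stratified)),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON (or YAML) file
#'
#' JSON is the primary dialect (jsonlite is a hard dependency); `.yaml` /
#' `.yml` files are accepted when the yaml package is installed. Fields
#' mirror [pipeline_config()] arguments; `synth` is a nested object of
#' [synth_config()] arguments.
#'
#' @param path Config file path.
#' @param outdir Override for the output directory (optional).
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(outdir)) raw$outdir <- outdir
  if (is.null(raw$outdir)) stop("config must define outdir")
  synth_args <- if (is.null(raw$synth)) list() else raw$synth
  raw$synth <- do.call(synth_config, synth_args)
  do.call(pipeline_config, raw)
}

pipeline_paths <- function(config) {
  out <- config$outdir
  list(enrichment = file.path(out, "enrichment.tsv"),
       features = file.path(out, "features.tsv"),
       ranked_prefix = file.path(out, "ranked"),
       maxrel = file.path(out, "ranked_maxrel.tsv"),
       mrmr = file.path(out, "ranked_mrmr.tsv"),
       ifs = file.path(out, "ifs.tsv"),
       ifs_curve = file.path(out, "ifs_curve.svg"),
       roc_curve = file.path(out, "roc_curve.svg"),
       optimal = file.path(out, "optimal_features.tsv"),
       manifest = file.path(out, "manifest.json"))
}

# recursively drop S3 classes so jsonlite serializes plain lists
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                         digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

stage_error <- function(stage, msg) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = sprintf("stage=%s code=STAGE_FAILED: %s",
                                        stage, msg),
                      call = NULL, stage = stage)))
}

#' Run the prediction pipeline
#'
#' Executes the requested stages in fixed order, persisting every
#' intermediate under `config$outdir`. A stage that is skipped (not listed in
#' `stages`) is served from its persisted artifact, so any suffix of the
#' pipeline can be re-run from disk. Rerunning with an identical config
#' produces byte-identical artifacts.
#'
#' @param config A [run_config][pipeline_config()].
#' @param stages Character vector of stages to execute, a subset of
#'   `c("synth", "enrich", "featurize", "rank", "ifs", "report")`, or
#'   `"all"`.
#' @return The manifest (named list), invisibly written as
#'   `<outdir>/manifest.json` by the `report` stage.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  if (identical(stages, "all")) stages <- .PIPELINE_STAGES
  if (!all(stages %in% .PIPELINE_STAGES)) {
    stop("unknown stage(s): ",
         paste(setdiff(stages, .PIPELINE_STAGES), collapse = ", "))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(config)
  manifest <- list(config = strip_classes(config),
                   config_hash = config_hash(config),
                   seeds = list(synth = config$synth$seed,
                                cv = config$cv_seed,
                                forest = config$forest_seed),
                   stages = list())
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage, info) {
    dt <- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
    pipeline_log(stage, "done in %.1fs", dt)
    manifest$stages[[stage]] <<- info
  }

  # --- synth / ingest ----------------------------------------------------
  if ("synth" %in% stages) {
    sd <- tryCatch(synth_generate(config$synth),
                   error = function(e) stage_error("synth", conditionMessage(e)))
    synth_write(sd, config$input_dir)
    inputs <- sd[c("drugs", "chem", "ppi", "annotation", "labels")]
    tick("synth", list(n_drugs = length(inputs$drugs),
                       chem_pairs = n_pairs(inputs$chem),
                       ppi_pairs = n_pairs(inputs$ppi),
                       n_pathways = length(inputs$annotation$pathways),
                       n_positives = nrow(inputs$labels$positives),
                       n_negatives = nrow(inputs$labels$negatives)))
  } else {
    inputs <- tryCatch(synth_read(config$input_dir, config$universe_size),
                       error = function(e) stage_error("ingest", conditionMessage(e)))
  }

  # --- enrich ------------------------------------------------------------
  if ("enrich" %in% stages) {
    profiles <- tryCatch(
      profile_all(inputs$drugs, inputs$ppi, inputs$annotation,
                  config$neighbor_threshold),
      error = function(e) stage_error("enrich", conditionMessage(e)))
    write_profiles(profiles, paths$enrichment)
    tick("enrich", list(rows = nrow(profiles), cols = ncol(profiles)))
  } else if (any(c("featurize") %in% stages)) {
    profiles <- read_profiles(paths$enrichment)
  }

  # --- featurize ---------------------------------------------------------
  if ("featurize" %in% stages) {
    pf <- tryCatch(
      build_matrix(inputs$labels, inputs$drugs, inputs$chem, inputs$ppi,
                   profiles),
      error = function(e) stage_error("featurize", conditionMessage(e)))
    write_feature_matrix(pf, paths$features)
    tick("featurize", list(rows = nrow(pf$features),
                           cols = ncol(pf$features)))
  } else if (any(c("rank", "ifs", "report") %in% stages)) {
    pf <- read_feature_matrix(paths$features)
  }

  # --- rank --------------------------------------------------------------
  if ("rank" %in% stages) {
    ranked <- tryCatch(rank_features(pf, variant = config$mrmr_variant),
                       error = function(e) stage_error("rank", conditionMessage(e)))
    write_ranked_lists(ranked, paths$ranked_prefix)
    tick("rank", list(n_features = length(ranked$mrmr)))
    mrmr_list <- ranked$mrmr
  } else if (any(c("ifs", "report") %in% stages)) {
    mrmr_list <- data.table::fread(paths$mrmr, sep = "\t")$feature
  }

  # --- ifs ---------------------------------------------------------------
  if ("ifs" %in% stages) {
    k_max <- if (is.null(config$k_max)) length(mrmr_list) else
      min(config$k_max, length(mrmr_list))
    ifs <- tryCatch(
      run_ifs(pf, mrmr_list = mrmr_list, k_max = k_max,
              folds = config$folds,
              config = forest_config(config$n_trees, config$m_try,
                                     config$forest_seed),
              cv_seed = config$cv_seed, stratified = config$stratified),
      error = function(e) stage_error("ifs", conditionMessage(e)))
    write_ifs_table(ifs, paths$ifs)
    plot_ifs_curve(ifs, paths$ifs_curve)
    plot_roc_curve(ifs, paths$roc_curve)
    best <- ifs$rows[k == ifs$optimal_k]
    tick("ifs", list(k_max = k_max, optimal_k = ifs$optimal_k,
                     mcc = best$mcc, acc = best$acc, auc = best$auc))
  } else if ("report" %in% stages) {
    ifs_rows <- data.table::fread(paths$ifs, sep = "\t")
    optimal_k <- ifs_rows[which.max(mcc), k]
    ifs <- list(rows = ifs_rows, optimal_k = optimal_k,
                optimal_features = mrmr_list[seq_len(optimal_k)])
  }

  # --- report ------------------------------------------------------------
  if ("report" %in% stages) {
    feat <- ifs$optimal_features
    kind <- rep("other", length(feat))
    kind[startsWith(feat, "sum:")] <- "sum"
    kind[startsWith(feat, "absdiff:")] <- "absdiff"
    pw <- ifelse(kind == "other", NA_character_,
                 sub("^(sum|absdiff):", "", feat))
    data.table::fwrite(data.table::data.table(
      rank = seq_along(feat), feature = feat, kind = kind, pathway = pw),
      paths$optimal, sep = "\t")
    artifact_files <- unlist(paths[c("enrichment", "features", "maxrel",
                                     "mrmr", "ifs", "optimal")])
    artifact_files <- artifact_files[file.exists(artifact_files)]
    manifest$artifacts <- as.list(tools::md5sum(artifact_files))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    tick("report", list(optimal_k = length(feat)))
  }

  invisible(manifest)
}

#' Command-line entry point
#'
#' Verbs: `synth`, `enrich`, `featurize`, `rank`, `ifs`, `report`, `all` —
#' each runs the corresponding stage (later stages read persisted
#' intermediates). Flags: `--config <file>` (JSON/YAML), `--outdir <dir>`,
#' plus overrides `--seed`, `--cv-seed`, `--forest-seed`, `--k-max`,
#' `--folds`, `--mrmr-variant`. Logs go to stderr.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return The manifest, invisibly.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    stop("usage: drugcombo <synth|enrich|featurize|rank|ifs|report|all> ",
         "[--config file] [--outdir dir] [--seed n] ...")
  }
  verb <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  config <- if (!is.null(opts$config)) {
    read_pipeline_config(opts$config, outdir = opts$outdir)
  } else {
    if (is.null(opts$outdir)) stop("--outdir (or --config) is required")
    pipeline_config(outdir = opts$outdir)
  }
  if (!is.null(opts$seed)) {
    config$synth$seed <- as.integer(opts$seed)
  }
  if (!is.null(opts$`cv-seed`)) config$cv_seed <- as.integer(opts$`cv-seed`)
  if (!is.null(opts$`forest-seed`)) {
    config$forest_seed <- as.integer(opts$`forest-seed`)
  }
  if (!is.null(opts$`k-max`)) config$k_max <- as.integer(opts$`k-max`)
  if (!is.null(opts$folds)) config$folds <- as.integer(opts$folds)
  if (!is.null(opts$`mrmr-variant`)) config$mrmr_variant <- opts$`mrmr-variant`
  stages <- if (verb == "all") "all" else verb
  run_pipeline(config, stages = stages)
}
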