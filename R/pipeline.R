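#' Pipeline stage commands
#'
#' The five pipeline stages behind the `rotaskip` command-line driver
#' (`inst/exec/rotaskip`). Each command is a pure function of its declared
#' inputs: given the same configuration (including its seed) it rewrites
#' identical outputs. Configurations are plain named lists; the driver
#' reads them from a YAML file with flag overrides.
#'
#' * `cmd_simulate` writes a synthetic study: genome FASTA, event TSV,
#'   per-tissue reads TSVs, truth labels TSV, and a config echo JSON.
#' * `cmd_extract` builds the feature table from genome + events + reads.
#' * `cmd_train` fits a Rotation Forest on a labelled feature table and
#'   serialises it to JSON.
#' * `cmd_predict` scores a feature table with a stored model.
#' * `cmd_evaluate` computes confusion metrics, ROC points and AUC from a
#'   predictions table.
#'
#' @param config named list; see the individual sections below for the
#'   recognised keys.
#' @return each command returns (invisibly) the paths it wrote.
#' @name pipeline
NULL

.need <- function(config, keys) {
  missing_keys <- setdiff(keys, names(config))
  if (length(missing_keys))
    stop("config is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
}

.need_file <- function(path, what) {
  if (!file.exists(path))
    stop("missing ", what, ": ", path)
  path
}

#' @rdname pipeline
#' @section cmd_simulate keys:
#' `out_dir`, `seed`, `n_es`, `n_non_es`; optional `depth`, `read_length`,
#' `anchor`, `psi_es` (list B/S), `psi_non_es`.
#' @export
cmd_simulate <- function(config) {
  .need(config, c("out_dir", "seed", "n_es", "n_non_es"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  args <- list(n_es = config$n_es, n_non_es = config$n_non_es,
               seed = config$seed)
  for (key in c("depth", "read_length", "anchor"))
    if (!is.null(config[[key]])) args[[key]] <- config[[key]]
  for (key in c("psi_es", "psi_non_es"))
    if (!is.null(config[[key]])) args[[key]] <- unlist(config[[key]])
  study <- do.call(simulate_es_study, args)
  paths <- file.path(config$out_dir,
                     c(genome = "genome.fa", events = "events.tsv",
                       reads_b = "reads_B.tsv", reads_s = "reads_S.tsv",
                       labels = "labels.tsv", config = "config.json"))
  names(paths) <- c("genome", "events", "reads_b", "reads_s", "labels",
                    "config")
  write_genome(study$genome, paths["genome"])
  write_events(study$events, paths["events"])
  write_reads_tsv(study$reads$B, paths["reads_b"])
  write_reads_tsv(study$reads$S, paths["reads_s"])
  utils::write.table(
    data.frame(event_id = study$events$event_id,
               label = as.character(study$labels)),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  echo <- c(args, list(
    total_mapped = list(B = study$meta$B$total_mapped,
                        S = study$meta$S$total_mapped)))
  jsonlite::write_json(echo, paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname pipeline
#' @section cmd_extract keys:
#' `genome`, `events`, `reads_b`, `reads_s`, `out` (feature TSV path),
#' `read_length`, `anchor`; optional `labels` (truth TSV to join),
#' `feature_set` (default `"rs"`), `total_mapped_b`, `total_mapped_s`
#' (default: number of read records per tissue).
#' @export
cmd_extract <- function(config) {
  .need(config, c("genome", "events", "reads_b", "reads_s", "out",
                  "read_length", "anchor"))
  genome <- read_genome(.need_file(config$genome, "genome FASTA"))
  events <- read_events(.need_file(config$events, "event table"))
  reads_b <- read_reads_tsv(.need_file(config$reads_b, "tissue-B reads"))
  reads_s <- read_reads_tsv(.need_file(config$reads_s, "tissue-S reads"))
  meta_b <- sample_meta("B", config$read_length, config$anchor,
                        config$total_mapped_b %||% max(1, nrow(reads_b)))
  meta_s <- sample_meta("S", config$read_length, config$anchor,
                        config$total_mapped_s %||% max(1, nrow(reads_s)))
  features <- build_feature_matrix(
    events, genome, reads_b = reads_b, reads_s = reads_s,
    meta_b = meta_b, meta_s = meta_s,
    feature_set = config$feature_set %||% "rs")
  labels <- NULL
  if (!is.null(config$labels)) {
    lab_tab <- utils::read.delim(.need_file(config$labels, "labels TSV"),
                                 stringsAsFactors = FALSE)
    labels <- lab_tab$label[match(rownames(features), lab_tab$event_id)]
  }
  write_feature_table(features, config$out, labels = labels)
  invisible(c(out = config$out))
}

#' @rdname pipeline
#' @section cmd_train keys:
#' `features` (labelled feature TSV), `out` (model JSON path), `seed`;
#' optional `n_trees`, `subset_size`, and the other [rotation_forest()]
#' arguments.
#' @export
cmd_train <- function(config) {
  .need(config, c("features", "out", "seed"))
  tab <- read_feature_table(.need_file(config$features, "feature table"))
  if (is.null(tab$labels))
    stop("training requires a feature table with a label column")
  args <- list(x = tab$features, y = tab$labels, seed = config$seed)
  for (key in c("n_trees", "subset_size", "class_sample_fraction",
                "bootstrap", "min_split", "min_leaf", "max_depth",
                "positive"))
    if (!is.null(config[[key]])) args[[key]] <- config[[key]]
  model <- do.call(rotation_forest, args)
  write_rotation_forest(model, config$out)
  invisible(c(out = config$out))
}

#' @rdname pipeline
#' @section cmd_predict keys:
#' `model` (model JSON), `features` (feature TSV), `out` (predictions TSV).
#' Output columns: `event_id`, `score` (positive-class confidence),
#' `pred_label`, and `true_label` when the feature table carries labels.
#' @export
cmd_predict <- function(config) {
  .need(config, c("model", "features", "out"))
  model <- read_rotation_forest(.need_file(config$model, "model file"))
  tab <- read_feature_table(.need_file(config$features, "feature table"))
  conf <- predict_confidence(model, tab$features)
  pred <- predict(model, tab$features)
  out <- data.frame(event_id = rownames(tab$features),
                    score = conf[, model$positive],
                    pred_label = as.character(pred),
                    stringsAsFactors = FALSE)
  if (!is.null(tab$labels)) out$true_label <- tab$labels
  utils::write.table(out, config$out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(out = config$out))
}

#' @rdname pipeline
#' @section cmd_evaluate keys:
#' `predictions` (TSV from `cmd_predict` with `true_label`), `out_metrics`
#' (JSON), `out_roc` (TSV); optional `positive` (default `"ES"`).
#' @export
cmd_evaluate <- function(config) {
  .need(config, c("predictions", "out_metrics", "out_roc"))
  tab <- utils::read.delim(.need_file(config$predictions, "predictions"),
                           stringsAsFactors = FALSE)
  for (col in c("score", "pred_label", "true_label"))
    if (!col %in% names(tab))
      stop("predictions table is missing column '", col, "'")
  positive <- config$positive %||% "ES"
  metrics <- classification_metrics(tab$pred_label, tab$true_label,
                                    scores = tab$score,
                                    positive = positive)
  jsonlite::write_json(
    list(confusion = as.list(metrics$confusion),
         accuracy_pct = metrics$accuracy,
         specificity_pct = metrics$specificity,
         sensitivity_pct = metrics$sensitivity,
         auc = metrics$auc,
         n = nrow(tab), positive = positive),
    config$out_metrics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(metrics$roc, config$out_roc, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(metrics = config$out_metrics, roc = config$out_roc))
}
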