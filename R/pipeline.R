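## End-to-end orchestration: predict / evaluate / simulate / report.
## Each run writes a machine-readable manifest (inputs, config, package
## version) sufficient to reproduce its outputs exactly. Progress and
## dropped-position logging goes to stderr via message().

default_config <- function() {
  list(percentile = 5, n_bins = 100, min_mutants = 10, k_sd = 1.0,
       cutoff = 5.0, clamp = TRUE, exclusions = integer(),
       numbering_offset = 0L, min_M = NULL, max_M = NULL)
}

#' Load a run configuration from JSON or YAML
#'
#' Unknown keys are rejected; missing keys take defaults (see
#' [run_predict] for the tunables and their meanings).
#'
#' @param path `.json` (always supported) or `.yaml`/`.yml` (requires the
#'   `yaml` package) file; `NULL` returns the defaults.
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  user <- if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_format("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, user)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(percentile > 0 && percentile < 100)) stop_validation("percentile out of (0, 100)")
    if (n_bins < 1) stop_validation("n_bins must be >= 1")
    if (min_mutants < 1) stop_validation("min_mutants must be >= 1")
    if (k_sd <= 0) stop_validation("k_sd must be > 0")
    if (cutoff < 0) stop_validation("cutoff must be >= 0")
  })
  invisible(cfg)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, dmsites_error = function(e) {
    stop_dmsites(class(e)[1], "stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

write_manifest <- function(out_dir, subcommand, inputs, cfg, outputs) {
  jsonlite::write_json(
    list(tool = "dmsites", subcommand = subcommand,
         package_version = as.character(utils::packageVersion("dmsites")),
         inputs = inputs, config = cfg, outputs = outputs),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Run the full prediction pipeline
#'
#' read scores -> fit rescaling anchors -> rescale -> average per
#' position (>= `min_mutants` filter) -> standardize and combine with
#' predicted accessibility -> three-class assignment at `k_sd` SD.
#' Anchors, dropped positions and calling thresholds are logged to
#' stderr.
#'
#' @param scores Path to a long-format score table, or a
#'   [mut_effect_table].
#' @param pred_acc Path to a predicted-accessibility table, or an
#'   [accessibility_table] with `source = "sequence_predicted"`.
#' @param config Path to a JSON/YAML config, or a named list as from
#'   [load_config]. Tunables: `percentile` (lower anchor percentile, 5),
#'   `n_bins` (peak-detection bins, 100), `min_mutants` (10), `k_sd`
#'   (call threshold in SDs, 1), `clamp` (TRUE), `exclusions` (positions
#'   excluded from the buried call), `numbering_offset` (integer added to
#'   accessibility-table positions to map them onto DMS numbering, 0),
#'   `min_M`/`max_M` (manual anchor override).
#' @param out_dir Optional output directory; when given, writes
#'   `predictions.tsv` and `run_manifest.json`.
#' @return A `prediction_table` (invisibly when `out_dir` is given).
#' @export
run_predict <- function(scores, pred_acc, config = NULL, out_dir = NULL) {
  cfg <- if (is.list(config)) utils::modifyList(default_config(), config) else load_config(config)
  validate_config(cfg)
  tab <- with_stage("read_scores", {
    if (inherits(scores, "mut_effect_table")) scores
    else read_mut_effect_table(scores, dialect = "long")
  })
  acc <- with_stage("read_accessibility", {
    if (inherits(pred_acc, "accessibility_table")) pred_acc
    else read_accessibility_table(pred_acc)
  })
  if (cfg$numbering_offset != 0L) {
    acc$position <- acc$position + as.integer(cfg$numbering_offset)
  }
  params <- with_stage("fit_rescale_params", {
    if (!is.null(cfg$min_M) && !is.null(cfg$max_M)) {
      rescale_params(cfg$min_M, cfg$max_M)
    } else {
      fit_rescale_params(tab$score, percentile = cfg$percentile,
                         n_bins = cfg$n_bins)
    }
  })
  message(sprintf("rescaling anchors: min_M = %.4g, max_M = %.4g",
                  params$min_M, params$max_M))
  rescaled <- with_stage("rescale", rescale_scores(tab, params, clamp = cfg$clamp))
  profiles <- with_stage("average_by_position",
                         average_by_position(rescaled, min_mutants = cfg$min_mutants))
  combined <- with_stage("combine", combine_scores(profiles, acc))
  pred <- with_stage("assign_classes",
                     assign_classes(combined, k = cfg$k_sd,
                                    exclusions = cfg$exclusions))
  th <- attr(pred, "thresholds")
  message(sprintf("call thresholds (k = %g): active > %.4f, buried > %.4f",
                  cfg$k_sd,
                  th$active$mean + th$active$k * th$active$sd,
                  th$buried$mean + th$buried$k * th$buried$sd))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_predictions(pred, file.path(out_dir, "predictions.tsv"))
    write_manifest(out_dir, "predict",
                   inputs = list(scores = if (is.character(scores)) scores else "<in-memory>",
                                 pred_acc = if (is.character(pred_acc)) pred_acc else "<in-memory>"),
                   cfg = cfg,
                   outputs = list(predictions = "predictions.tsv",
                                  anchors = list(min_M = params$min_M,
                                                 max_M = params$max_M)))
    return(invisible(pred))
  }
  pred
}

#' Evaluate a prediction table against truth labels
#'
#' @param pred Path to a predictions TSV, or a `prediction_table`.
#' @param truth Path to a truth-label TSV, or a [residue_truth].
#' @param out_dir Optional output directory; when given, writes
#'   `metrics.tsv` and `run_manifest.json`.
#' @param dataset_id Label for the report rows.
#' @return A `metrics_report` (one row per class).
#' @export
run_evaluate <- function(pred, truth, out_dir = NULL, dataset_id = NA_character_) {
  p <- with_stage("read_predictions", {
    if (inherits(pred, "prediction_table")) pred else read_predictions(pred)
  })
  t <- with_stage("read_truth", {
    if (inherits(truth, "residue_truth")) truth else read_truth(truth)
  })
  report <- with_stage("evaluate", evaluate_predictions(p, t, dataset_id))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_report(report, file.path(out_dir, "metrics.tsv"))
    write_manifest(out_dir, "evaluate",
                   inputs = list(pred = if (is.character(pred)) pred else "<in-memory>",
                                 truth = if (is.character(truth)) truth else "<in-memory>"),
                   cfg = list(), outputs = list(metrics = "metrics.tsv"))
    return(invisible(report))
  }
  report
}

#' Generate a synthetic dataset on disk
#'
#' @param config A [synthetic_config], a named list of its arguments, or
#'   a path to a JSON/YAML file of them.
#' @param out_dir Output directory.
#' @return Invisibly, the list returned by [simulate_dataset].
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- with_stage("config", {
    if (inherits(config, "synthetic_config")) config
    else if (is.list(config)) do.call(synthetic_config, config)
    else {
      raw <- if (grepl("\\.(yaml|yml)$", config)) yaml::read_yaml(config)
             else jsonlite::read_json(config, simplifyVector = TRUE)
      do.call(synthetic_config, raw)
    }
  })
  invisible(simulate_dataset(cfg, out_dir))
}

#' Aggregate metrics reports across datasets
#'
#' Binds per-dataset metric rows and appends an unweighted `MEAN` row per
#' class — the cross-dataset summary in which each dataset counts
#' equally.
#'
#' @param reports List of `metrics_report` objects or paths to
#'   `metrics.tsv` files written by [run_evaluate].
#' @param out Optional output TSV path.
#' @return A `data.frame` with per-dataset rows plus `MEAN` rows.
#' @export
run_report <- function(reports, out = NULL) {
  rows <- lapply(reports, function(r) {
    if (is.character(r)) {
      df <- utils::read.table(r, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      df <- df[df$dataset != "MEAN", , drop = FALSE]
      data.frame(dataset = df$dataset, class = df$class,
                 sensitivity = as.numeric(df$sensitivity_pct) / 100,
                 specificity = as.numeric(df$specificity_pct) / 100,
                 accuracy = as.numeric(df$accuracy_pct) / 100,
                 mcc = as.numeric(df$mcc), stringsAsFactors = FALSE)
    } else {
      r[, c("dataset", "class", "sensitivity", "specificity", "accuracy", "mcc")]
    }
  })
  all_rows <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(unique(all_rows$class), function(cl) {
    m <- summarize_datasets(all_rows[all_rows$class == cl,
                                     c("sensitivity", "specificity", "accuracy", "mcc")])
    data.frame(dataset = "MEAN", class = cl,
               sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
               accuracy = m[["accuracy"]], mcc = m[["mcc"]],
               stringsAsFactors = FALSE)
  }))
  out_df <- rbind(all_rows, summary)
  if (!is.null(out)) {
    fmt <- out_df
    for (col in c("sensitivity", "specificity", "accuracy")) {
      fmt[[col]] <- sprintf("%.1f", 100 * fmt[[col]])
    }
    fmt$mcc <- sprintf("%.2f", fmt$mcc)
    names(fmt)[3:5] <- paste0(names(out_df)[3:5], "_pct")
    utils::write.table(fmt, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out_df
}
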