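# End-to-end pipeline: discover -> segment -> profile -> train/evaluate.

#' Pipeline run configuration
#'
#' @param input_dir Directory of two-channel image pairs (see
#'   [discover_images()] for the naming convention).
#' @param output_dir Directory for all artifacts (created if needed).
#' @param blind_dir Optional directory of unlabelled image pairs to predict.
#' @param segmentation A [segmentation_params()].
#' @param classifiers Named list of [classifier_spec()]s.
#' @param split_fraction Held-out split training share.
#' @param cv_folds Cross-validation folds.
#' @param seed Integer seed recorded in every artifact.
#' @param learning_curves Compute learning curves (slower).
#' @param verbose Per-stage progress messages.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir, blind_dir = NULL,
                            segmentation = segmentation_params(),
                            classifiers = default_classifiers(),
                            split_fraction = 0.5, cv_folds = 10, seed = 1,
                            learning_curves = FALSE, verbose = TRUE) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 blind_dir = blind_dir, segmentation = segmentation,
                 classifiers = classifiers, split_fraction = split_fraction,
                 cv_folds = cv_folds, seed = as.integer(seed),
                 learning_curves = learning_curves, verbose = verbose),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; nested
#' `segmentation` keys override [segmentation_params()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, y$segmentation %||% list())
  pipeline_config(
    input_dir = y$input_dir, output_dir = y$output_dir,
    blind_dir = y$blind_dir, segmentation = seg,
    split_fraction = y$split_fraction %||% 0.5,
    cv_folds = y$cv_folds %||% 10, seed = y$seed %||% 1,
    learning_curves = isTRUE(y$learning_curves),
    verbose = y$verbose %||% TRUE
  )
}

#' Run the full phenotyping pipeline
#'
#' Discovers labelled image pairs, segments nuclei and cell bodies, computes
#' the 228-measurement cytoprofile per cell, trains and evaluates the
#' classifier panel, and writes the feature table, evaluation report (JSON),
#' confusion/ROC CSVs, figures and a provenance file (config hash, seed,
#' schema hash) to `output_dir`. If `blind_dir` is set, predictions for the
#' unlabelled images are written as well. Idempotent for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return The `cyto_eval` report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  schema <- feature_schema()

  records <- discover_images(config$input_dir)
  say("[discover] %d image pairs", nrow(records))
  features <- profile_dataset(records, config$segmentation, schema,
                              verbose = config$verbose)
  say("[profile] %d cells x %d features", nrow(features),
      length(feature_columns(features)))
  write_feature_table(features, file.path(config$output_dir, "feature_table.csv"))
  write.csv(schema, file.path(config$output_dir, "feature_schema.csv"),
            row.names = FALSE)

  report <- evaluate_classifiers(features, config$classifiers,
                                 split_fraction = config$split_fraction,
                                 folds = config$cv_folds, seed = config$seed,
                                 learning_curves = config$learning_curves)
  say("[evaluate] best CV accuracy %.1f%%",
      max(vapply(report$cv, `[[`, numeric(1), "overall")))

  # reports and figures
  out <- config$output_dir
  jsonlite::write_json(
    list(cv = lapply(report$cv, function(e)
      list(per_class = e$per_class, overall = e$overall,
           confusion = as.data.frame(e$confusion))),
      holdout = lapply(report$holdout, function(e)
        list(per_class = e$per_class, overall = e$overall)),
      auc = lapply(report$roc, `[[`, "auc"),
      n_cells = report$n_cells, seed = report$seed),
    file.path(out, "evaluation_report.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(report$cv)) {
    write.csv(report$cv[[nm]]$confusion,
              file.path(out, paste0("confusion_cv_", nm, ".csv")))
    write.csv(report$roc[[nm]]$curves,
              file.path(out, paste0("roc_", nm, ".csv")), row.names = FALSE)
  }
  ggplot2::ggsave(file.path(out, "fig_accuracy.png"),
                  autoplot.cyto_eval(report, "accuracy"), width = 7, height = 4, dpi = 120)
  ggplot2::ggsave(file.path(out, "fig_confusion.png"),
                  autoplot.cyto_eval(report, "confusion"), width = 6, height = 5, dpi = 120)
  ggplot2::ggsave(file.path(out, "fig_roc.png"),
                  autoplot.cyto_eval(report, "roc"), width = 6, height = 5, dpi = 120)

  if (!is.null(config$blind_dir)) {
    blind_rec <- discover_images(config$blind_dir)
    blind_feats <- profile_dataset(blind_rec, config$segmentation, schema)
    model <- fit_classifier(config$classifiers$random_forest %||%
                              config$classifiers[[1]], features)
    preds <- predict_blind(model, blind_feats)
    write.csv(preds, file.path(out, "blind_predictions.csv"), row.names = FALSE)
    say("[blind] %d cells predicted", nrow(preds))
  }

  cfg_for_hash <- config[setdiff(names(config), "verbose")]
  jsonlite::write_json(
    list(seed = config$seed, config_hash = rlang::hash(cfg_for_hash),
         schema_hash = schema_hash(schema), n_images = nrow(records),
         n_cells = report$n_cells, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out, "provenance.json"), auto_unbox = TRUE)
  invisible(report)
}
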