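#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end pipeline (simulate ->
#' preprocess -> features -> select -> train-ml [-> train-cnn]) in one
#' round-trippable list. Defaults are the study conditions the package
#' simulates: a 21 AS / 13 non-AS cohort, 0.8-25 Hz band-pass, 0.5-s RMS
#' step with a 1.5x-median cutoff, 10-s segments, a 0.79-25.39 Hz Morse
#' CWT grid.
#'
#' @param n_per_class named subjects-per-class vector.
#' @param duration_s,fs_hz recording length and sampling rate.
#' @param segment_s,threshold,rms_step_s segmentation parameters.
#' @param band_hz band-pass edges.
#' @param voices_per_octave CWT grid density.
#' @param channels channels to extract features from.
#' @param l1_ratio,cv_folds elastic-net parameters.
#' @param family,scheme,ratio classifier family, validation scheme
#'   (`"loso"` or `"ldo"`), and leave-data-out ratio.
#' @param grid classifier grid (default [default_grid()] of `family`).
#' @param cnn a [cnn_config()] (used only when the cnn stage runs).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_class = c(AS = 21, NON_AS = 13),
                            duration_s = 300, fs_hz = 256,
                            segment_s = 10, threshold = 1.5,
                            rms_step_s = 0.5, band_hz = c(0.8, 25),
                            voices_per_octave = 16,
                            channels = c("SCG_Z", "GCG_Y"),
                            l1_ratio = 0.5, cv_folds = 5,
                            family = "XGB", scheme = "loso", ratio = 0.2,
                            grid = NULL, cnn = cnn_config(), seed = 1) {
  structure(list(
    n_per_class = n_per_class, duration_s = duration_s, fs_hz = fs_hz,
    segment_s = segment_s, threshold = threshold, rms_step_s = rms_step_s,
    band_hz = band_hz, voices_per_octave = voices_per_octave,
    channels = channels, l1_ratio = l1_ratio, cv_folds = cv_folds,
    family = family, scheme = scheme, ratio = ratio,
    grid = grid %||% default_grid(family), cnn = unclass(cnn), seed = seed
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' All stage parameters round-trip through the file unchanged.
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  raw$n_per_class <- as.list(raw$n_per_class)  # keep names in YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$n_per_class <- unlist(raw$n_per_class)
  do.call(pipeline_config, c(raw[setdiff(names(raw), "cnn")],
                             list(cnn = do.call(cnn_config, raw$cnn))))
}

PIPELINE_STAGES <- c("simulate", "preprocess", "features", "select",
                     "train_ml", "train_cnn")

#' Run the pipeline end-to-end
#'
#' Executes the requested stages in order, writing one artifact per
#' stage under `out_dir` plus a JSON manifest (configuration, its hash,
#' seed, artifact paths, and metric summaries). A stage whose upstream
#' artifact is missing (because an earlier stage was neither requested
#' nor previously run into the same directory) raises a
#' stage-dependency error. Rerunning with the same configuration and
#' seed reproduces the artifacts.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate","preprocess","features","select","train_ml","train_cnn")`.
#'   The cnn stage is opt-in.
#' @param out_dir output directory.
#' @return the manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, stages = c("simulate", "preprocess",
                                            "features", "select",
                                            "train_ml"),
                         out_dir = tempfile("cardiowave_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(out_dir, "cohort"),
    segments = file.path(out_dir, "segments_index.csv"),
    segments_rds = file.path(out_dir, "segments.rds"),
    features = file.path(out_dir, "feature_table.csv"),
    selection = file.path(out_dir, "selection.json"),
    report = file.path(out_dir, "ml_report.json"),
    cnn_report = file.path(out_dir, "cnn_report.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  need <- function(path, stage, upstream) {
    if (!file.exists(path)) {
      abort(sprintf("stage '%s' needs artifact '%s' from stage '%s'",
                    stage, path, upstream),
            class = "cardiowave_stage_dependency_error")
    }
  }
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    stages = stages,
    artifacts = list(),
    summaries = list()
  )

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(config$n_per_class, config$duration_s,
                              config$fs_hz, config$seed)
    write_cohort_csv(cohort, paths$cohort)
    manifest$artifacts$simulate <- paths$cohort
  }
  if ("preprocess" %in% stages) {
    need(file.path(paths$cohort, "metadata.csv"), "preprocess", "simulate")
    cohort <- read_cohort_csv(paths$cohort)
    segments <- segment_cohort(cohort, config$channels, config$segment_s,
                               config$threshold, config$rms_step_s)
    readr::write_csv(
      mutate(select(segments, -"samples"),
             n_samples = lengths(segments$samples)),
      paths$segments)
    saveRDS(segments, paths$segments_rds)
    manifest$artifacts$preprocess <- paths$segments
  }
  if ("features" %in% stages) {
    need(paths$segments_rds, "features", "preprocess")
    segments <- readRDS(paths$segments_rds)
    grid <- build_cwt_grid(config$fs_hz, config$voices_per_octave)
    table <- build_feature_table(segments, grid, config$channels)
    readr::write_csv(table, paths$features)
    manifest$artifacts$features <- paths$features
    manifest$summaries$features <- list(
      n_segments = nrow(table),
      n_features = length(feature_columns(table)))
  }
  if ("select" %in% stages) {
    need(paths$features, "select", "features")
    table <- readr::read_csv(paths$features, show_col_types = FALSE)
    sel <- elastic_net_select(table, config$l1_ratio, config$cv_folds,
                              config$seed)
    jsonlite::write_json(
      list(selected = sel$selected_names,
           coefficients = as.list(sel$coefficients),
           n_original = sel$n_original, n_selected = sel$n_selected,
           reduction_pct = sel$reduction_pct),
      paths$selection, auto_unbox = TRUE, digits = NA)
    manifest$artifacts$select <- paths$selection
    manifest$summaries$select <- list(n_selected = sel$n_selected,
                                      reduction_pct = sel$reduction_pct)
  }
  if ("train_ml" %in% stages) {
    need(paths$features, "train_ml", "features")
    table <- readr::read_csv(paths$features, show_col_types = FALSE)
    report <- if (config$scheme == "loso") {
      evaluate_loso(table, config$family, config$grid, seed = config$seed)
    } else {
      evaluate_leave_data_out(table, config$family, config$grid,
                              ratio = config$ratio, seed = config$seed)
    }
    jsonlite::write_json(
      list(scheme = report$scheme, family = report$model_family,
           accuracy = report$accuracy,
           per_class = report$per_class,
           confusion = as.data.frame(report$confusion)),
      paths$report, auto_unbox = TRUE, digits = NA)
    manifest$artifacts$train_ml <- paths$report
    manifest$summaries$train_ml <- list(scheme = report$scheme,
                                        accuracy = report$accuracy)
  }
  if ("train_cnn" %in% stages) {
    need(paths$segments_rds, "train_cnn", "preprocess")
    segments <- readRDS(paths$segments_rds)
    segments <- filter(segments, .data$channel == config$channels[1])
    grid <- build_cwt_grid(config$fs_hz, config$voices_per_octave)
    shape <- c(60, 80)
    imgs <- array(0, dim = c(shape, nrow(segments)))
    for (i in seq_len(nrow(segments))) {
      sc <- cwt_morse(segments$samples[[i]], segments$fs_hz[i], grid)
      imgs[, , i] <- render_image(sc, "GRAY_1CH", shape)[, , 1]
    }
    labels <- factor(segments$class_label)
    cfg <- do.call(cnn_config, config$cnn)
    report <- train_cnn(imgs, labels, config = cfg)
    jsonlite::write_json(
      list(scheme = report$scheme, accuracy = report$accuracy,
           fold_accuracies = report$fold_accuracies),
      paths$cnn_report, auto_unbox = TRUE, digits = NA)
    manifest$artifacts$train_cnn <- paths$cnn_report
    manifest$summaries$train_cnn <- list(accuracy = report$accuracy)
  }

  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
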