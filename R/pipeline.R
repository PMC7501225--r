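## End-to-end pipeline: configuration handling, cohort simulation to disk,
## and the simulate -> sample -> mirror -> cross-validate -> report chain.
## These functions back the thin command-line wrapper in
## inst/scripts/craniorays-cli.R.

run_config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "craniorays-output",
    synth = list(counts = c(healthy = 53L, scaphocephaly = 76L,
                            trigonocephaly = 40L, plagiocephaly = 27L),
                 severity_range = c(0.5, 1), scale_range_mm = c(55, 75),
                 noise_amp_mm = 1, frequency = 16L),
    sphere = list(frequency = 12L),
    features = list(scaling = "fold", miss = "error"),
    model = as.list(unclass(classifier_config())),
    eval = list(k = 10L, eval_mode = "original", validation = "inner")
  )
}

#' Build or load a pipeline run configuration
#'
#' A run configuration nests the cohort specification, sampling-sphere
#' frequency, feature options, classifier hyperparameters and evaluation
#' options under one master seed.  `run_config()` merges overrides into the
#' defaults; unknown keys are rejected.  `read_run_config()` loads a YAML
#' file; `write_run_config()` saves one.
#'
#' @param ... Named overrides of top-level sections (`seed`, `output_dir`,
#'   `synth`, `sphere`, `features`, `model`, `eval`); list-valued sections
#'   are merged key-wise.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) overrides <- overrides[[1]]
  merge_section <- function(base, over, path) {
    bad <- setdiff(names(over), names(base))
    if (length(bad))
      stop("unknown configuration key(s): ",
           paste(paste0(path, bad), collapse = ", "))
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) && !is.null(names(base[[nm]])))
        base[[nm]] <- merge_section(base[[nm]], over[[nm]], paste0(path, nm, "."))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_section(cfg, overrides, "")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth$counts)) raw$synth$counts <- unlist(raw$synth$counts)
  run_config(raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_to_cohort_spec <- function(config) {
  cohort_spec(counts = config$synth$counts,
              severity_range = config$synth$severity_range,
              scale_range_mm = config$synth$scale_range_mm,
              noise_amp_mm = config$synth$noise_amp_mm,
              seed = config$seed,
              frequency = config$synth$frequency)
}

config_to_classifier <- function(config) {
  do.call(classifier_config,
          config$model[names(config$model) %in% names(formals(classifier_config))])
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort of the configuration and writes one ASCII
#' PLY mesh per subject plus a `manifest.csv` (subject_id, class, severity,
#' scale_mm, seed, file) into `output_dir/meshes`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest data.frame.
#' @export
cmd_simulate <- function(config = run_config()) {
  dir <- file.path(config$output_dir, "meshes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config_to_cohort_spec(config))
  files <- file.path(dir, paste0(cohort$manifest$subject_id, ".ply"))
  for (i in seq_along(cohort$meshes)) write_mesh(cohort$meshes[[i]], files[i])
  manifest <- cbind(cohort$manifest, file = files, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Run the full pipeline
#'
#' Simulate (or load) a cohort, sample the ray descriptors, mirror, run
#' linked stratified k-fold cross-validation, and write the report:
#' aggregated and per-fold confusion matrices (CSV), a metrics table (CSV),
#' and a JSON run record with the resolved configuration, seeds and
#' per-stage timings.
#'
#' @param config A [run_config()].
#' @param meshes Optional pre-built cohort (as from [generate_cohort()]);
#'   otherwise the synthetic cohort of the configuration is generated.
#' @param write Write report files under `config$output_dir` (default TRUE).
#' @param verbose Progress messages.
#' @return The [crossvalidate()] result, invisibly when `write = TRUE`.
#' @export
cmd_pipeline <- function(config = run_config(), meshes = NULL, write = TRUE,
                         verbose = TRUE) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(...)
  if (config$features$scaling == "all" || config$eval$validation == "test-fold")
    say("NOTE: replication mode (",
        if (config$features$scaling == "all") "all-subject scaling" else "",
        if (config$features$scaling == "all" && config$eval$validation == "test-fold") ", " else "",
        if (config$eval$validation == "test-fold") "test-fold validation" else "",
        "): reported metrics are not leakage-free")

  t0 <- tic()
  cohort <- meshes %||% generate_cohort(config_to_cohort_spec(config))
  timings["simulate"] <- tic() - t0
  say(sprintf("simulate: %d meshes [%.1f s]", length(cohort$meshes), timings["simulate"]))

  t0 <- tic()
  sphere <- build_hemisphere(config$sphere$frequency)
  feats <- cohort_features(cohort, sphere, miss = config$features$miss)
  timings["sample"] <- tic() - t0
  say(sprintf("sample: %d x %d descriptor rows [%.1f s]",
              nrow(feats$lengths), ncol(feats$lengths), timings["sample"]))

  t0 <- tic()
  cv <- crossvalidate(feats, config_to_classifier(config),
                      k = config$eval$k, seed = config$seed,
                      scaling = config$features$scaling,
                      eval_mode = config$eval$eval_mode,
                      validation = config$eval$validation,
                      verbose = verbose)
  timings["crossvalidate"] <- tic() - t0
  say(sprintf("crossvalidate: accuracy %.1f%% [%.1f s]",
              100 * cv$metrics$accuracy, timings["crossvalidate"]))

  if (write) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(unclass(cv$confusion)),
              file.path(config$output_dir, "confusion.csv"))
    for (f in seq_along(cv$per_fold))
      write.csv(as.data.frame(unclass(cv$per_fold[[f]])),
                file.path(config$output_dir, sprintf("confusion_fold%02d.csv", f)))
    write.csv(cv$metrics$per_class,
              file.path(config$output_dir, "metrics.csv"), row.names = FALSE)
    write.csv(cv$predictions,
              file.path(config$output_dir, "predictions.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), timings = as.list(timings),
           accuracy = cv$metrics$accuracy,
           finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file.path(config$output_dir, "run_record.json"),
      auto_unbox = TRUE, pretty = TRUE)
    return(invisible(cv))
  }
  cv
}

#' Metrics from a stored confusion matrix
#'
#' Reads a 4x4 confusion-matrix CSV (rows = true class, columns = predicted;
#' a leading row-name column is accepted) and returns the standard metric
#' set.
#'
#' @param path CSV file path.
#' @return A [confusion_metrics()] object.
#' @export
metrics_from_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!is.numeric(df[[1]])) {
    rownames(df) <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  if (is.null(rownames(m)) || all(rownames(m) == as.character(seq_len(nrow(m)))))
    rownames(m) <- colnames(m)
  confusion_metrics(m)
}
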