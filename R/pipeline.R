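#' Run the full registration/identification pipeline
#'
#' Chains every stage — simulate (or read) walking sequences, segment gait
#' cycles, build tensors, cross-validated training (registration) and
#' scoring of held-out sequences with frozen weights (identification) — from
#' a single configuration, and optionally writes a report directory. The
#' configuration is a nested list (or path to a YAML file) with blocks:
#'
#' * `simulate`: arguments of [simulate_population()] (`n_subjects`,
#'   `sequences_per_subject`, `duration`, `fps`, `separation`, `noise_sd`);
#'   alternatively `input_dir`: a directory of canonical skeleton CSV files.
#' * `segmentation`: arguments of [segment_cycles()].
#' * `model`: arguments of [model_config()] except `classes`.
#' * `train`: `k`, `optimizer`, `lr`, `batch_size`, `epochs`,
#'   `validation_split`, `level`.
#' * `seed`: one integer propagated to every stage.
#' * `output_dir`: where to write `report.json`, `folds.csv`, `cmc.csv`,
#'   `roc.csv`, `history.csv` and a `config.yaml` snapshot (optional).
#'
#' @param config Nested list or path to a YAML file.
#' @param verbose Print stage progress?
#' @return The [cross_validate()] report (`gait_cv`), invisibly when
#'   `output_dir` is set.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("simulate", "input_dir", "segmentation", "model", "train",
             "seed", "output_dir", "schema")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    abort(paste0("Unknown config block(s): ", paste(extra, collapse = ", ")))
  }
  if (is.null(config$simulate) && is.null(config$input_dir)) {
    abort("Config must provide either `simulate` parameters or an `input_dir`.")
  }
  seed <- config$seed %||% 1L
  stage <- function(what, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", what, "' failed: ", conditionMessage(e)))
    })
    if (verbose) {
      inform(sprintf("[%s] done in %.1fs", what, proc.time()[["elapsed"]] - t0))
    }
    r
  }
  sequences <- stage("acquire", {
    if (!is.null(config$input_dir)) {
      files <- list.files(config$input_dir, pattern = "\\.(csv|txt)$",
                          full.names = TRUE)
      files <- files[basename(files) != "manifest.csv"]
      if (!length(files)) abort(paste0("No sequence files in ", config$input_dir))
      lapply(files, read_skeleton_csv)
    } else {
      do.call(simulate_population, c(config$simulate, list(seed = seed)))
    }
  })
  dataset <- stage("segment+tensors", {
    do.call(assemble_dataset, c(list(sequences), config$segmentation))
  })
  if (verbose) {
    inform(sprintf("dataset: %d cycles from %d subjects",
                   nrow(dataset), n_classes(dataset)))
  }
  mcfg <- do.call(model_config,
                  c(list(classes = n_classes(dataset)), config$model))
  tr <- config$train %||% list()
  cv <- stage("cross-validate", {
    do.call(cross_validate,
            c(list(dataset = dataset, config = mcfg, seed = seed,
                   verbose = verbose), tr))
  })
  if (!is.null(config$output_dir)) {
    write_report(cv, config$output_dir, config)
    return(invisible(cv))
  }
  cv
}

#' Write a cross-validation report directory
#'
#' @param cv A `gait_cv`.
#' @param dir Output directory (created if needed).
#' @param config Optional resolved configuration to snapshot alongside.
#' @return `dir`, invisibly.
#' @export
write_report <- function(cv, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- glance(cv)
  jsonlite::write_json(as.list(g), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(cv$folds, file.path(dir, "folds.csv"), row.names = FALSE)
  utils::write.csv(cv$cmc, file.path(dir, "cmc.csv"), row.names = FALSE)
  utils::write.csv(cv$roc$curve, file.path(dir, "roc.csv"), row.names = FALSE)
  utils::write.csv(cv$history, file.path(dir, "history.csv"), row.names = FALSE)
  if (!is.null(config)) {
    yaml::write_yaml(config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
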