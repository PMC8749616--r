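#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end pipeline: output locations, the
#' cohort design and effect model of the simulator, and the color,
#' texture, and selection configurations. The configuration hash recorded
#' in every artifact is computed over all of it.
#'
#' @param out_dir directory for pipeline artifacts.
#' @param seed integer master seed.
#' @param design a [cohort_design()] (its seed is overridden by `seed`).
#' @param effect an [effect_model()].
#' @param palette a [palette_spec()].
#' @param color_cfg a [color_config()].
#' @param texture_cfg a [texture_config()].
#' @param selection_cfg a [selection_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = "thermotex_run", seed = 1L,
                       design = cohort_design(),
                       effect = effect_model(),
                       palette = default_thermal_palette(),
                       color_cfg = color_config(),
                       texture_cfg = texture_config(),
                       selection_cfg = selection_config()) {
  design$seed <- as.integer(seed)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), design = design,
              effect = effect, palette = palette, color_cfg = color_cfg,
              texture_cfg = texture_cfg, selection_cfg = selection_cfg)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the scalar configuration keys (seed, output directory, design
#' counts and schedules, image shape, selection alphas, texture settings)
#' from a YAML file and builds a [run_config()]; keys not present keep
#' their defaults.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  pick <- function(lst, keys) lst[intersect(names(lst), keys)]
  design <- do.call(cohort_design, pick(y$design %||% list(),
    c("n_nonpregnant", "n_pregnant_per_subgroup", "months_subgroup_a",
      "months_subgroup_b", "n_sessions_nonpregnant", "image_shape")))
  sel <- do.call(selection_config, pick(y$selection %||% list(),
    c("alpha", "normality_alpha", "c2_method", "drop_glch")))
  tex <- do.call(texture_config, pick(y$texture %||% list(),
    c("gray_levels", "offset", "log_base", "window_radii")))
  run_config(out_dir = y$out_dir %||% "thermotex_run",
             seed = seed %||% y$seed %||% 1L,
             design = design, selection_cfg = sel, texture_cfg = tex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

artifact_paths <- function(cfg) {
  list(cohort_dir = file.path(cfg$out_dir, "cohort"),
       features = file.path(cfg$out_dir, "features.csv"),
       selection = file.path(cfg$out_dir, "selection.csv"),
       stage_counts = file.path(cfg$out_dir, "stage_counts.json"),
       accuracy = file.path(cfg$out_dir, "accuracy.csv"))
}

pipe_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its artifact into, the
#' configured output directory: `pipeline_simulate` writes the synthetic
#' cohort (frames, mask, metadata), `pipeline_extract` the feature table,
#' `pipeline_select` the selection table plus stage-count JSON, and
#' `pipeline_evaluate` the accuracy table. [run_pipeline()] chains them.
#'
#' @param cfg a [run_config()].
#' @param verbose emit progress messages.
#' @return the stage's main result, invisibly for the writers.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(cfg = run_config(), verbose = FALSE) {
  paths <- artifact_paths(cfg)
  cohort <- generate_cohort(cfg$design, cfg$effect, cfg$palette)
  write_cohort(cohort, paths$cohort_dir)
  pipe_log(verbose, "simulate: wrote %d frames to %s",
           nrow(cohort$metadata), paths$cohort_dir)
  invisible(cohort)
}

#' @rdname pipeline
#' @export
pipeline_extract <- function(cfg = run_config(), verbose = FALSE) {
  paths <- artifact_paths(cfg)
  cohort <- read_cohort(paths$cohort_dir)
  features <- extract_cohort_features(cohort, cfg$texture_cfg, cfg$color_cfg)
  write_artifact_csv(features, paths$features, cfg$seed, cfg$hash)
  pipe_log(verbose, "extract: wrote %d feature records", nrow(features))
  invisible(features)
}

#' @rdname pipeline
#' @export
pipeline_select <- function(cfg = run_config(), verbose = FALSE) {
  paths <- artifact_paths(cfg)
  features <- read_artifact_csv(paths$features)
  sel <- run_selection(features, cfg$selection_cfg)
  write_artifact_csv(sel$results, paths$selection, cfg$seed, cfg$hash)
  jsonlite::write_json(c(list(seed = cfg$seed, config_hash = cfg$hash),
                         sel$stage_counts),
                       paths$stage_counts, auto_unbox = TRUE)
  pipe_log(verbose,
           "select: %d enumerated, %d after criterion 1, %d after criterion 2, %d final",
           sel$stage_counts$enumerated, sel$stage_counts$after_c1,
           sel$stage_counts$after_c2, sel$stage_counts$final)
  invisible(sel)
}

#' @rdname pipeline
#' @export
pipeline_evaluate <- function(cfg = run_config(), verbose = FALSE) {
  paths <- artifact_paths(cfg)
  features <- read_artifact_csv(paths$features)
  selection <- read_artifact_csv(paths$selection)
  selection$selected <- as.logical(selection$selected)
  selection$pass_c1 <- as.logical(selection$pass_c1)
  acc <- evaluate_accuracy(features, selection)
  write_artifact_csv(acc, paths$accuracy, cfg$seed, cfg$hash)
  pipe_log(verbose, "evaluate: wrote %d accuracy records", nrow(acc))
  invisible(acc)
}

#' Run the pipeline end to end
#'
#' @param command one of `"simulate"`, `"extract"`, `"select"`,
#'   `"evaluate"`, `"all"`.
#' @param cfg a [run_config()].
#' @param verbose emit progress messages.
#' @return invisibly, the last stage's result.
#' @export
run_pipeline <- function(command = c("all", "simulate", "extract", "select",
                                     "evaluate"),
                         cfg = run_config(), verbose = FALSE) {
  command <- match.arg(command)
  steps <- if (command == "all") {
    c("simulate", "extract", "select", "evaluate")
  } else command
  res <- NULL
  for (s in steps) {
    res <- switch(s,
      simulate = pipeline_simulate(cfg, verbose),
      extract = pipeline_extract(cfg, verbose),
      select = pipeline_select(cfg, verbose),
      evaluate = pipeline_evaluate(cfg, verbose))
  }
  invisible(res)
}
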