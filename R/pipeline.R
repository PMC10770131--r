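#' End-to-end run configuration
#'
#' One flat configuration object covering every pipeline stage. Unknown keys
#' are rejected by name, so a config file travels safely between versions.
#'
#' @param n_pd,n_hc,n_dd Synthetic cohort sizes.
#' @param seed Global seed; per-stage seeds are derived deterministically from
#'   it by stage-name hashing (see [run_pipeline()]).
#' @param task Classification task, `c("PD", "HC")` or `c("PD", "DD")`.
#' @param outer_k,inner_k Fold counts.
#' @param trim_seconds,trend_lambda,removed_steps Preprocessing parameters.
#' @param input_sources,options,classifiers Grid axes (see [default_grid()]).
#' @param n_repeats Permutation-importance repeats.
#' @param out_dir Output directory for artifacts.
#' @param verbose Print stage progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_pd = 20, n_hc = 20, n_dd = 0, seed = 1L,
                       task = c("PD", "HC"), outer_k = 5, inner_k = 5,
                       trim_seconds = 0.5, trend_lambda = 1e4,
                       removed_steps = default_removed_steps(),
                       input_sources = c("acceleration", "rotation", "both"),
                       options = "A", classifiers = c("svm", "gbt"),
                       n_repeats = 10, out_dir = tempfile("watchpd_run_"),
                       verbose = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' @param path Path to a JSON file whose keys are [run_config()] arguments.
#'   Unknown keys are rejected with the offending name.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess/featurize -> nested-CV evaluation ->
#' classifier stacking -> grouped importance, writing all artifacts (feature
#' matrix, reports, importance table) plus a manifest recording the
#' configuration, derived stage seeds and artifact checksums to
#' `config$out_dir`. Reruns with an identical configuration reproduce
#' identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the evaluation report, the stacked report,
#'   the importance table and the manifest path.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  stage_seed <- function(stage) derive_seed(config$seed, stage)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage simulate (seed ", stage_seed("simulate"), ")")
  cohort <- run_stage("simulate", {
    gc <- generator_config(n_pd = config$n_pd, n_hc = config$n_hc,
                           n_dd = config$n_dd, seed = stage_seed("simulate"))
    generate_cohort(gc)
  })

  say("stage preprocess/featurize")
  data <- run_stage("featurize", {
    pc <- preprocess_config(trim_seconds = config$trim_seconds,
                            trend_lambda = config$trend_lambda,
                            removed_steps = config$removed_steps)
    build_cohort_data(cohort, pc)
  })
  feat_file <- file.path(config$out_dir, "features_manual.csv")
  utils::write.csv(as.data.frame(data$manual), feat_file)
  info_file <- file.path(config$out_dir, "features_manual_columns.json")
  jsonlite::write_json(attr(data$manual, "col_info"), info_file)

  grid <- default_grid(config$input_sources, config$options,
                       config$classifiers)
  say("stage evaluate (seed ", stage_seed("evaluate"), ")")
  report <- run_stage("evaluate",
    evaluate_nested(data, config$task, grid, config$outer_k, config$inner_k,
                    seed = stage_seed("evaluate")))
  report_file <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report$folds, report_file, digits = NA)

  say("stage stack (seed ", stage_seed("stack"), ")")
  stacked <- run_stage("stack",
    evaluate_stack(data, config$task, grid, outer_k = config$outer_k,
                   inner_k = config$inner_k, seed = stage_seed("stack")))
  stacked_file <- file.path(config$out_dir, "report_stacked.json")
  jsonlite::write_json(stacked$folds, stacked_file, digits = NA)

  say("stage importance (seed ", stage_seed("importance"), ")")
  best <- stacked$folds[stacked$folds$modality == "stacked", ]
  best_row <- best[which.max(best$balanced_accuracy), ]
  sensor_setup <- grid_point(best_row$input_source, best_row$option,
                             best_row$classifier)
  imp <- run_stage("importance",
    stack_importance(data, config$task, sensor_setup,
                     outer_k = config$outer_k, inner_k = config$inner_k,
                     seed = stage_seed("importance"),
                     n_repeats = config$n_repeats))
  imp_file <- file.path(config$out_dir, "importance.json")
  jsonlite::write_json(rank_groups(imp), imp_file, digits = NA)

  cfg_file <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config)[setdiff(names(config),
                                               c("out_dir", "verbose"))],
                       cfg_file, auto_unbox = TRUE, digits = NA)
  artifacts <- c(cfg_file, feat_file, info_file, report_file, stacked_file,
                 imp_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stage_seeds = sapply(c("simulate", "evaluate", "stack", "importance"),
                         stage_seed),
    artifacts = stats::setNames(as.list(unname(tools::md5sum(artifacts))),
                                basename(artifacts))
  )
  manifest_file <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE)
  say("wrote manifest ", manifest_file)
  invisible(list(report = report, stacked = stacked, importance = imp,
                 manifest = manifest_file, out_dir = config$out_dir))
}
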