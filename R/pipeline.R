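#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected. The configuration can also be loaded from a YAML file
#' with [read_pipeline_config()].
#'
#' @param cohort_csv Optional path to a cohort CSV; when `NULL` a synthetic
#'   cohort is simulated from `spec`.
#' @param spec A [default_study_spec()]-style list used when simulating.
#' @param n Cohort size for simulation (default `spec$n`).
#' @param seed Root integer seed; all randomness in the run flows from it.
#' @param encode_variables Optional variable subset for [encode_cohort()].
#' @param autocm An [autocm_params()] object.
#' @param acs An [acs_params()] object; default clamps the Framingham score.
#' @param exclude_elements If `TRUE`, the ACS stage prunes the 31 single
#'   element variables (the composite toxicity index is retained); the
#'   semantic map itself is never pruned.
#' @param toxicity_weights Optional named toxicity-weight overrides.
#' @param out_dir Output directory for the run artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_csv = NULL, spec = default_study_spec(),
                            n = NULL, seed = 1L, encode_variables = NULL,
                            autocm = autocm_params(),
                            acs = acs_params("framingham"),
                            exclude_elements = FALSE,
                            toxicity_weights = NULL,
                            out_dir = tempfile("autocmap_run_")) {
  cfg <- list(cohort_csv = cohort_csv, spec = spec, n = n,
              seed = as.integer(seed), encode_variables = encode_variables,
              autocm = autocm, acs = acs,
              exclude_elements = isTRUE(exclude_elements),
              toxicity_weights = toxicity_weights, out_dir = out_dir)
  stopifnot(inherits(cfg$autocm, "autocm_params"),
            inherits(cfg$acs, "acs_params"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the scalar fields of [pipeline_config()] plus nested `autocm:` and
#' `acs:` blocks whose keys match [autocm_params()] / [acs_params()]
#' arguments. Unknown keys raise an error. The cohort size is spelled
#' `n_subjects` in YAML (a bare `n` is a boolean in YAML 1.1).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("cohort_csv", "n_subjects", "seed", "encode_variables", "autocm",
             "acs", "exclude_elements", "toxicity_weights", "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort_autocmap(paste0("Unknown config keys: ",
                          paste(unknown, collapse = ", ")),
                   "autocmap_schema_error")
  }
  check_sub <- function(block, fn_args, label) {
    bad <- setdiff(names(block), fn_args)
    if (length(bad) > 0) {
      abort_autocmap(paste0("Unknown ", label, " config keys: ",
                            paste(bad, collapse = ", ")),
                     "autocmap_schema_error")
    }
  }
  check_sub(y$autocm, names(formals(autocm_params)), "autocm")
  check_sub(y$acs, names(formals(acs_params)), "acs")
  autocm <- do.call(autocm_params, y$autocm %||% list())
  acs <- do.call(acs_params, y$acs %||% list(clamp_variable = "framingham"))
  tw <- if (!is.null(y$toxicity_weights)) unlist(y$toxicity_weights)
  pipeline_config(cohort_csv = y$cohort_csv, n = y$n_subjects,
                  seed = y$seed %||% 1L,
                  encode_variables = y$encode_variables,
                  autocm = autocm, acs = acs,
                  exclude_elements = y$exclude_elements %||% FALSE,
                  toxicity_weights = tw,
                  out_dir = y$out_dir %||% tempfile("autocmap_run_"))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_autocmap(paste0("Pipeline stage `", stage, "` failed: ",
                          conditionMessage(e)),
                   "autocmap_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates the full chain: cohort (simulated or read from CSV) ->
#' per-subject indices -> encoding -> Auto-CM training -> link strengths ->
#' semantic connectivity map -> ACS perturbation run. Emits nine artifacts
#' into `config$out_dir`: `cohort.csv`, `indices.csv`, `encoded.csv`,
#' `linkstrengths.csv`, `map.graphml`, `map.dot`, `acs_trajectories.csv`,
#' `acs_hierarchy.json` and `run_log.txt`. The run is fully reproducible from
#' the configuration and seed; any stage failure aborts with a stage-tagged
#' error, leaving earlier artifacts in place for inspection.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly, with the stage results attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  cohort <- pipeline_stage("cohort", {
    if (!is.null(config$cohort_csv)) read_cohort_csv(config$cohort_csv)
    else simulate_cohort(config$spec, n = config$n, seed = config$seed,
                         toxicity_weights = config$toxicity_weights)
  })
  write_cohort_csv(cohort, p("cohort.csv"))

  indices <- pipeline_stage("indices", {
    cohort_indices(cohort,
                   config$toxicity_weights %||% default_toxicity_weights())
  })
  readr::write_csv(indices, p("indices.csv"))

  encoded <- pipeline_stage("encode", {
    encode_cohort(cohort, variables = config$encode_variables)
  })
  readr::write_csv(tibble::as_tibble(unclass(encoded)), p("encoded.csv"))

  model <- pipeline_stage("autocm", train_autocm(encoded, config$autocm))
  strengths <- pipeline_stage("strengths", link_strengths(model))
  readr::write_csv(tidy(strengths), p("linkstrengths.csv"))

  map <- pipeline_stage("map", semantic_map(strengths_to_distances(strengths)))
  export_map(map, p("map.graphml"), "graphml")
  export_map(map, p("map.dot"), "dot")

  acs_res <- pipeline_stage("acs", {
    prm <- config$acs
    if (config$exclude_elements && is.null(prm$variable_subset)) {
      prm$variable_subset <- setdiff(colnames(strengths),
                                     element_schema()$symbol)
    }
    run_acs(strengths, prm)
  })
  export_acs(acs_res, p("acs_trajectories.csv"), "csv")
  export_acs(acs_res, p("acs_hierarchy.json"), "json")

  writeLines(c(
    paste0("autocmap version: ", as.character(utils::packageVersion("autocmap"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("cohort: ", if (is.null(config$cohort_csv)) "simulated"
           else config$cohort_csv),
    paste0("subjects: ", nrow(cohort)),
    paste0("encoded variables: ", ncol(encoded)),
    paste0("autocm epochs: ", model$epochs_run,
           " (converged: ", model$converged, ")"),
    paste0("central node: ", map$central_node),
    paste0("acs clamp: ", acs_res$clamp,
           " (converged: ", acs_res$converged, ")")
  ), p("run_log.txt"))

  out <- config$out_dir
  attr(out, "results") <- list(cohort = cohort, indices = indices,
                               encoded = encoded, model = model,
                               strengths = strengths, map = map,
                               acs = acs_res)
  invisible(out)
}
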