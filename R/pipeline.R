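# One-command pipeline: simulate -> build cohort -> per-contrast nuisances,
# CV-TMLE and comparators -> sensitivity variants -> reports. A single global
# seed fans out to per-stage seeds by fixed offsets so stages can be rerun
# reproducibly.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()] for the synthetic population.
#' @param study A [study_config()].
#' @param model A [model_config()] (used when `nuisance_engine` is
#'   `"transformer"`).
#' @param nuisance_engine `"glm"` for cross-fitted logistic nuisances on
#'   cohort features, `"transformer"` for the EHR sequence model.
#' @param glm_features Model terms used by the glm engine (complete
#'   history-derived cohort features by default, see
#'   [history_glm_features()]).
#' @param tmle_variant `"pooled"` or `"per_fold"` fluctuation.
#' @param mice_m,mice_iterations Imputation count and chained cycles for the
#'   adjusted-logistic comparator.
#' @param covariate_set `"main"` or `"extended"` adjustment set.
#' @param sensitivity Character vector of sensitivity-variant names (see
#'   [apply_sensitivity_filter()]), applied to the CV-TMLE analysis.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim, study = study_config(), model = model_config(),
                       nuisance_engine = c("glm", "transformer"),
                       glm_features = history_glm_features(),
                       tmle_variant = "pooled",
                       mice_m = 5L, mice_iterations = 5L,
                       covariate_set = "main",
                       sensitivity = character(0), seed = 1L) {
  structure(list(sim = sim, study = study, model = model,
                 nuisance_engine = match.arg(nuisance_engine),
                 glm_features = glm_features, tmle_variant = tmle_variant,
                 mice_m = as.integer(mice_m),
                 mice_iterations = as.integer(mice_iterations),
                 covariate_set = covariate_set, sensitivity = sensitivity,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `sim`, `study`, `model` hold the arguments of the
#' respective constructors; remaining keys are passed to [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$covariate_effects)) {
    sim_args$covariate_effects <- unlist(sim_args$covariate_effects)
  }
  args <- y[setdiff(names(y), c("sim", "study", "model"))]
  args$sim <- do.call(sim_config, sim_args)
  args$study <- do.call(study_config, y$study %||% list())
  args$model <- do.call(model_config, y$model %||% list())
  do.call(run_config, args)
}

rr_estimate_json <- function(e) {
  keep <- c("rr", "ci_low", "ci_high", "log_se", "epsilon", "score_residual",
            "method", "contrast", "n1", "n0", "events1", "events0",
            "psi1", "psi0", "hr", "schoenfeld_p", "global_p", "ci_fold_only")
  out <- unclass(e)[intersect(keep, names(unclass(e)))]
  out
}

contrast_nuisances <- function(cohort, population, category, config) {
  if (config$nuisance_engine == "transformer") {
    mc <- config$model
    mc$seed <- derive_seed(config$seed, 300L + category)
    train_crossfit(cohort, population, category, mc)
  } else {
    crossfit_glm_nuisances(cohort, category, config$glm_features,
                           delta = config$model$propensity_clip)
  }
}

#' Run the full analysis pipeline
#'
#' Simulates a population, builds the analysis cohort, and for each of the
#' five SBP contrasts computes cross-fitted nuisances, the CV-TMLE risk
#' ratio, the crude and adjusted-logistic comparators and the Cox check;
#' then applies any configured sensitivity variants to the CV-TMLE analysis
#' and writes `cohort.csv`, `flow.json`, `estimates.json`, `forest.csv`,
#' `summary.csv` and `forest.pdf` under `out_dir`. Reruns with the same
#' configuration are identical.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @param out_dir Output directory.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the population, cohort, flow, estimates,
#'   forest table and summary.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("run_pipeline seed=%d started %s\n", config$seed,
              format(Sys.time())), file = log_path)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "ehrtmle_pipeline_error")
    })
    msg <- sprintf("[%s] %.1fs", name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")))
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
    res
  }

  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 1L)
  population <- stage("simulate", generate_population(sim))
  built <- stage("build_cohort",
                 build_cohort(population, config$study,
                              fold_seed = derive_seed(config$seed, 2L)))
  cohort <- built$cohort
  imps <- stage("mice", mice_impute(cohort, m = config$mice_m,
                                    iterations = config$mice_iterations,
                                    seed = derive_seed(config$seed, 4L),
                                    extra_continuous =
                                      if (config$covariate_set == "extended")
                                        "hba1c_mean_12m" else character(0)))
  estimates <- list()
  for (cat in 1:5) {
    nm <- sprintf("cat%d", cat)
    nuis <- stage(paste0("nuisance_", nm),
                  contrast_nuisances(cohort, population, cat, config))
    estimates[[paste0("cv_tmle_", nm)]] <-
      stage(paste0("cv_tmle_", nm),
            cv_tmle_rr(nuis, contrast = sprintf("cat%d_vs_ref", cat),
                       variant = config$tmle_variant))
    estimates[[paste0("crude_", nm)]] <- stage(paste0("crude_", nm),
                                               crude_rr(cohort, cat))
    estimates[[paste0("adjusted_lr_", nm)]] <-
      stage(paste0("adjusted_lr_", nm),
            adjusted_lr_rr(cohort, cat, imps, config$covariate_set))
    estimates[[paste0("cox_", nm)]] <-
      stage(paste0("cox_", nm),
            cox_hazard_check(imps$completed[[1]], cat, config$covariate_set,
                             config = config$study))
  }
  sens <- list()
  for (v in config$sensitivity) {
    sub <- stage(paste0("sensitivity_", v),
                 apply_sensitivity_filter(cohort, v, population, config$study,
                                          fold_seed = derive_seed(config$seed, 2L)))
    for (cat in 1:5) {
      nuis <- contrast_nuisances(sub, population, cat, config)
      sens[[sprintf("%s_cat%d", v, cat)]] <-
        cv_tmle_rr(nuis, contrast = sprintf("cat%d_vs_ref", cat),
                   variant = config$tmle_variant)
    }
  }

  forest <- render_forest_table(estimates, built$flow$per_category)
  summary_tab <- summarize_cohort(cohort, config$study)
  write_cohort(cohort, built$flow, out_dir)
  write.csv(forest, file.path(out_dir, "forest.csv"), row.names = FALSE, na = "")
  write.csv(summary_tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(main = lapply(estimates, rr_estimate_json),
         sensitivity = lapply(sens, rr_estimate_json)),
    file.path(out_dir, "estimates.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  sch <- estimates[["cox_cat5"]]$residuals
  if (!is.null(sch)) {
    write.csv(sch, file.path(out_dir, "schoenfeld_residuals.csv"),
              row.names = FALSE)
  }
  grDevices::pdf(file.path(out_dir, "forest.pdf"), width = 7, height = 5)
  print(plot_forest(forest))
  grDevices::dev.off()
  cat("done\n", file = log_path, append = TRUE)
  invisible(list(population = population, cohort = cohort, flow = built$flow,
                 estimates = estimates, sensitivity = sens, forest = forest,
                 summary = summary_tab, out_dir = out_dir))
}
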