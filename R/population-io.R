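# Delimited-text writers/readers for synthetic populations and cohorts.
# All round-trip losslessly: read_population(write_population(x)) == x.

patient_col_classes <- c(
  pid = "character", sex = "character", birth_day = "numeric",
  smoking = "character", censor_day = "numeric", death_day = "numeric",
  death_cause = "character", bmi = "numeric", hdl = "numeric",
  total_chol = "numeric", triglycerides = "numeric", hba1c = "numeric",
  diabetes_duration = "numeric", cv_event_day = "numeric",
  latent_u = "numeric", latent_sbp_mean = "numeric", latent_cat = "integer",
  latent_y = "integer",
  risk_cat0 = "numeric", risk_cat1 = "numeric", risk_cat2 = "numeric",
  risk_cat3 = "numeric", risk_cat4 = "numeric", risk_cat5 = "numeric")

#' Write a synthetic population to delimited text
#'
#' Writes `patients.csv`, `events.csv`, `measurements.csv` and a ground-truth
#' sidecar `truth.json` carrying the per-category true marginal risks and
#' risk ratios (finite-population means of the stored potential risks), the
#' configuration echo and the seed.
#'
#' @param population An `ehr_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(population$patients, file.path(dir, "patients.csv"),
            row.names = FALSE, quote = TRUE, na = "")
  write.csv(population$events, file.path(dir, "events.csv"),
            row.names = FALSE, quote = TRUE, na = "")
  write.csv(population$measurements, file.path(dir, "measurements.csv"),
            row.names = FALSE, quote = TRUE, na = "")
  risk <- as.matrix(population$patients[paste0("risk_cat", 0:5)])
  psi <- colMeans(risk)
  cfg_echo <- unclass(population$config)
  cfg_echo$covariate_effects <- as.list(cfg_echo$covariate_effects)
  truth <- list(true_marginal_risks = as.numeric(psi),
                true_rr = as.numeric(psi / psi[1]),
                seed = population$config$seed,
                config = cfg_echo)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

read_csv_typed <- function(path, classes) {
  df <- read.csv(path, colClasses = classes, na.strings = "",
                 stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Read a population written by [write_population()]
#'
#' @param dir Directory containing the delimited files and `truth.json`.
#' @return An `ehr_population`.
#' @export
read_population <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  cfg <- truth$config
  cfg$covariate_effects <- unlist(cfg$covariate_effects)
  config <- do.call(sim_config, cfg)
  structure(list(
    patients = read_csv_typed(file.path(dir, "patients.csv"), patient_col_classes),
    events = read_csv_typed(file.path(dir, "events.csv"),
                            c(pid = "character", day = "numeric",
                              code = "character", modality = "character")),
    measurements = read_csv_typed(file.path(dir, "measurements.csv"),
                                  c(pid = "character", day = "numeric",
                                    sbp = "numeric")),
    config = config), class = "ehr_population")
}

#' Write an analysis cohort and its patient-flow accounting
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param flow `flow_counts` from [build_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, flow, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE, na = "")
  fl <- unclass(flow)
  fl$per_category <- as.data.frame(fl$per_category)
  jsonlite::write_json(fl, file.path(dir, "flow.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(dir)
}
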