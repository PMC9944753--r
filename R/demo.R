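# Reverse-causation demonstration: one replicate of the frailty-confounded
# scenario analysed by every method, used by the test suite, the acceptance
# script and the worked examples.

#' Default history-derived features for logistic nuisance models
#'
#' Model terms summarising the pre-entry coded history (the frailty-linked
#' comorbidity recordings and overall contact intensity) plus fully observed
#' baseline covariates; all are complete columns of the built cohort.
#' Baseline treatment flags are deliberately excluded: they predict the
#' exposure far more strongly than the outcome, and such instrument-like
#' covariates are known to amplify residual confounding bias in
#' propensity-based estimators.
#'
#' @return Character vector of formula terms.
#' @export
history_glm_features <- function() {
  c("age_at_entry", "sex", "comorb_count", "log1p(comorb_count)",
    "af", "ckd", "log1p(n_dx_prior)", "log1p(n_rx_prior)")
}

#' One replicate of the J-shape demonstration
#'
#' Simulates the frailty-confounded scenario ([sim_config_jshape()]), builds
#' the cohort, and estimates the full RR sequence (categories 1..5 vs the
#' <120 mm Hg reference) with the crude estimator, complete-case adjusted
#' logistic regression (main covariate set), and CV-TMLE with cross-fitted
#' logistic nuisances on the history features. The finite-population true RR
#' sequence is computed from the stored potential risks.
#'
#' @param n_patients Simulated population size.
#' @param seed Replicate seed.
#' @param features Nuisance model terms (see [history_glm_features()]).
#' @return A list of numeric length-5 vectors `crude`, `lr`, `tmle`, `true`,
#'   plus `n_final`.
#' @export
jshape_replicate <- function(n_patients = 20000, seed = 1,
                             features = history_glm_features()) {
  cfg <- sim_config_jshape(n_patients, seed = derive_seed(seed, 51L))
  pop <- generate_population(cfg)
  built <- build_cohort(pop, fold_seed = derive_seed(seed, 52L))
  cohort <- built$cohort
  crude <- vapply(1:5, function(k) crude_rr(cohort, k)$rr, numeric(1))
  cc_cols <- c("bmi", "hdl", "total_chol", "triglycerides", "smoking")
  cc <- cohort[complete.cases(cohort[cc_cols]), ]
  lr <- vapply(1:5, function(k)
    adjusted_lr_rr(cc, k, covariate_set = "main")$rr, numeric(1))
  tmle <- vapply(1:5, function(k)
    cv_tmle_rr(crossfit_glm_nuisances(cohort, k, features),
               contrast = sprintf("cat%d_vs_ref", k))$rr, numeric(1))
  psi <- colMeans(as.matrix(pop$patients[paste0("risk_cat", 0:5)]))
  list(crude = crude, lr = lr, tmle = tmle,
       true = unname(psi[-1] / psi[1]), n_final = nrow(cohort))
}

#' Shape diagnostics of an RR sequence
#'
#' `interior_minimum`: the minimum of the sequence `(1, rr1..rr5)` is
#' attained strictly between the reference and the top category (the
#' J-shape signature). `monotone`: the five estimated contrasts are
#' non-decreasing (the no-J-shape signature).
#'
#' @param rr Numeric length-5 vector of RR estimates vs the reference.
#' @return List with logicals `interior_minimum` and `monotone`.
#' @export
rr_shape <- function(rr) {
  stopifnot(length(rr) == 5)
  full <- c(1, rr)
  list(interior_minimum = which.min(full) %in% 2:5,
       monotone = all(diff(rr) >= 0))
}
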