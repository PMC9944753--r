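# Conventional comparators: crude risk ratios, adjusted logistic regression
# with direct standardization over k-fold test sets (Rubin-combined across
# imputations), and a Cox proportional-hazards check.

MAIN_COVARIATES <- c("age_at_entry", "sex", "smoking", "bmi",
                     "antihypertensive_baseline", "hdl", "total_chol",
                     "triglycerides", "af", "ckd")
EXTENDED_COVARIATES <- c(MAIN_COVARIATES, "insulin_baseline", "hba1c_mean_12m",
                         "diabetes_duration")

#' Crude risk ratio for one exposure contrast
#'
#' Ratio of raw event proportions between a comparison category and the
#' reference, with the textbook log-RR variance
#' `1/a - 1/n1 + 1/c - 1/n0`.
#'
#' @param cohort Cohort tibble.
#' @param category Comparison exposure category in 1..5.
#' @return An `rr_estimate` with method `"crude"`.
#' @export
crude_rr <- function(cohort, category) {
  sub <- pairwise_subset(cohort, category)
  n1 <- sum(sub$arm == 1); n0 <- sum(sub$arm == 0)
  a <- sum(sub$outcome[sub$arm == 1]); cc <- sum(sub$outcome[sub$arm == 0])
  if (n1 == 0 || n0 == 0) {
    abort("Both exposure groups must be nonempty.",
          class = "ehrtmle_estimation_error")
  }
  if (cc == 0) {
    abort("Zero events in the reference group; crude RR undefined.",
          class = "ehrtmle_estimation_error")
  }
  rr <- (a / n1) / (cc / n0)
  log_se <- sqrt(1 / a - 1 / n1 + 1 / cc - 1 / n0)
  new_rr_estimate(rr = rr, ci_low = exp(log(rr) - 1.96 * log_se),
                  ci_high = exp(log(rr) + 1.96 * log_se), log_se = log_se,
                  method = "crude", contrast = sprintf("cat%d_vs_ref", category),
                  n1 = n1, n0 = n0, events1 = a, events0 = cc)
}

covariate_set_columns <- function(covariate_set = c("main", "extended"),
                                  none = FALSE) {
  if (none) return(character(0))
  switch(match.arg(covariate_set), main = MAIN_COVARIATES,
         extended = EXTENDED_COVARIATES)
}

# Logistic fit with a ridge fallback when separation is detected.
fit_outcome_logistic <- function(form, data) {
  fit <- suppressWarnings(glm(form, data = data, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (!sep) return(list(predict = function(nd)
    predict(fit, newdata = nd, type = "response")))
  warn("Separation detected in a training fold; refitting with a ridge penalty.")
  X <- model.matrix(form, data)[, -1, drop = FALSE]
  y <- stats::model.response(stats::model.frame(form, data))
  rfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 1e-2)
  trms <- stats::delete.response(stats::terms(form, data = data))
  list(predict = function(nd) {
    Xn <- model.matrix(trms, nd)[, -1, drop = FALSE]
    as.vector(predict(rfit, newx = Xn, type = "response"))
  })
}

#' Adjusted logistic-regression risk ratio via direct standardization
#'
#' For each imputation and each cross-validation fold, fits a logistic
#' outcome model (arm indicator + covariates) on the training folds and
#' standardizes on the test fold: `psi_a` is the mean predicted risk with the
#' arm forced to `a` over the test-fold patients, and the fold RR is
#' `psi1/psi0`. The point estimate is the mean of the fold RRs averaged over
#' imputations; the 95% CI combines the dispersion of the fold log-RRs
#' (normal approximation) with between-imputation variance by a Rubin-style
#' rule. A fold-variance-only CI is reported alongside in `ci_fold_only`.
#'
#' @param cohort Cohort tibble (pairwise restriction applied internally;
#'   folds must be assigned).
#' @param category Comparison exposure category in 1..5.
#' @param imputations An `imputation_set` from [mice_impute()] built on the
#'   same cohort, or `NULL` to use the cohort as-is (complete data).
#' @param covariate_set `"main"` or `"extended"`.
#' @param exposure_only If `TRUE`, fit the exposure indicator alone (no
#'   covariates) — the standardized RR then reproduces the training-fold
#'   crude RR.
#' @param covariates Optional character vector of model terms overriding the
#'   named covariate set (formula syntax, e.g. `c("af", "arm:af")`).
#' @return An `rr_estimate` with method `"adjusted_lr"`, plus `fold_rrs`
#'   and `ci_fold_only` diagnostics.
#' @export
adjusted_lr_rr <- function(cohort, category, imputations = NULL,
                           covariate_set = "main", exposure_only = FALSE,
                           covariates = NULL) {
  covs <- covariates %||% covariate_set_columns(covariate_set,
                                                none = exposure_only)
  tables <- if (is.null(imputations)) list(cohort) else imputations$completed
  form <- as.formula(paste("outcome ~ arm",
                           if (length(covs)) paste("+", paste(covs, collapse = " + "))
                           else ""))
  per_imp <- lapply(tables, function(tab) {
    sub <- pairwise_subset(tab, category)
    folds <- sort(unique(sub$fold))
    vapply(folds, function(f) {
      tr <- sub[sub$fold != f, ]
      te <- sub[sub$fold == f, ]
      fit <- fit_outcome_logistic(form, tr)
      te1 <- te; te1$arm <- 1L
      te0 <- te; te0$arm <- 0L
      mean(fit$predict(te1)) / mean(fit$predict(te0))
    }, numeric(1))
  })
  m <- length(per_imp)
  k <- length(per_imp[[1]])
  logs <- lapply(per_imp, log)
  q_m <- vapply(logs, mean, numeric(1))
  var_m <- vapply(logs, function(l) var(l) / k, numeric(1))
  qbar <- mean(q_m)
  w <- mean(var_m)
  b <- if (m > 1) var(q_m) else 0
  tot <- w + (1 + 1 / m) * b
  rr <- mean(unlist(per_imp))
  new_rr_estimate(
    rr = rr,
    ci_low = exp(qbar - 1.96 * sqrt(tot)),
    ci_high = exp(qbar + 1.96 * sqrt(tot)),
    log_se = sqrt(tot), method = "adjusted_lr",
    contrast = sprintf("cat%d_vs_ref", category),
    n1 = sum(cohort$exposure_cat == category),
    n0 = sum(cohort$exposure_cat == 0),
    events1 = sum(cohort$outcome[cohort$exposure_cat == category]),
    events0 = sum(cohort$outcome[cohort$exposure_cat == 0]),
    extra = list(fold_rrs = per_imp,
                 ci_fold_only = exp(qbar + c(-1.96, 1.96) * sqrt(w))))
}

#' Cox proportional-hazards check
#'
#' Fits a Cox model (Efron ties) on follow-up time from the end of the
#' exposure period, with the same predictors as the adjusted logistic model,
#' and tests proportional hazards on the scaled Schoenfeld residuals.
#' Rows with missing covariates are dropped (pass a completed imputation to
#' avoid this).
#'
#' @inheritParams adjusted_lr_rr
#' @param config The [study_config()] defining the follow-up window.
#' @return A list with `hr`, `ci_low`, `ci_high`, `schoenfeld_p` (arm term),
#'   `global_p`, `residuals` (tibble of scaled Schoenfeld residuals vs time,
#'   for plotting/export) and the fitted `survival::coxph` object.
#' @export
cox_hazard_check <- function(cohort, category, covariate_set = "main",
                             exposure_only = FALSE, config = study_config()) {
  sub <- pairwise_subset(cohort, category)
  end_day <- sub$entry_day + config$followup_end_day
  stop_day <- pmin(ifelse(is.na(sub$event_day), Inf, sub$event_day),
                   ifelse(is.na(sub$censor_day), Inf, sub$censor_day), end_day)
  sub$time <- stop_day - (sub$entry_day + config$followup_start_day)
  sub$status <- sub$outcome
  if (sum(sub$status) == 0) {
    abort("No events; Cox model undefined.", class = "ehrtmle_estimation_error")
  }
  covs <- covariate_set_columns(covariate_set, none = exposure_only)
  form <- as.formula(paste("survival::Surv(time, status) ~ arm",
                           if (length(covs)) paste("+", paste(covs, collapse = " + "))
                           else ""))
  dat <- sub[stats::complete.cases(sub[c("time", "status", "arm", covs)]), ]
  fit <- survival::coxph(form, data = dat, ties = "efron")
  zph <- survival::cox.zph(fit)
  sm <- summary(fit)
  res <- tibble::as_tibble(as.data.frame(zph$y))
  res$time <- zph$time
  list(hr = unname(exp(coef(fit)["arm"])),
       ci_low = unname(sm$conf.int["arm", "lower .95"]),
       ci_high = unname(sm$conf.int["arm", "upper .95"]),
       schoenfeld_p = unname(zph$table["arm", "p"]),
       global_p = unname(zph$table["GLOBAL", "p"]),
       residuals = res, fit = fit,
       contrast = sprintf("cat%d_vs_ref", category))
}
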