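# Synthetic longitudinal EHR cohorts with known counterfactual risks.
#
# A latent frailty U ~ N(0,1) drives (i) emission of designated comorbidity
# codes in the pre-entry history, (ii) the patient-specific mean SBP, and
# (iii) the outcome log-odds, so crude SBP-outcome contrasts are confounded
# while the per-patient potential risks under each exposure category are
# stored as ground truth.

DX_OUTCOME_CODES <- c("dx_ihd", "dx_hf", "dx_stroke")
DX_FLAG_CODES <- c("dx_af", "dx_ckd")
DX_COMORB_CODES <- paste0("dx_comorb", 1:5)
RX_SPECIAL_CODES <- c("rx_antihtn", "rx_insulin")

#' Simulation configuration for synthetic EHR cohorts
#'
#' Defines the data-generating process: cohort size, the confounding strength
#' of the latent frailty on SBP and on the outcome, per-category additive
#' exposure effects on the outcome log-odds (reference category fixed at 0),
#' measurement/dropout intensities, and the entry window.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the whole population is deterministic given it.
#' @param vocab_size_dx,vocab_size_rx Sizes of the synthetic diagnosis and
#'   medication code vocabularies (including the designated special codes).
#' @param conf_strength Effect of the latent frailty on the outcome log-odds
#'   (per SD of frailty).
#' @param sbp_conf_slope Effect of the latent frailty on the patient's mean
#'   SBP, in mm Hg per SD of frailty. Positive makes frail patients
#'   hypertensive; negative (frail patients with low SBP) produces the
#'   J-shape-inducing confounding pattern.
#' @param category_effects Numeric vector of 6 additive log-odds effects of
#'   the exposure category on the outcome; the first (reference, <120 mm Hg)
#'   must be 0.
#' @param baseline_logodds Intercept of the outcome model.
#' @param covariate_effects Named numeric vector of log-odds effects for
#'   `age` (per year, centred at 65), `sex_M`, `smoking_former`,
#'   `smoking_current`, `bmi` (per unit, centred at 29), `af`, `ckd`.
#' @param sbp_mean,sbp_between_sd Population mean SBP and between-patient SD
#'   of the patient-specific mean (mm Hg).
#' @param sbp_noise_sd Within-patient measurement noise SD (mm Hg).
#' @param measurement_rate Expected SBP measurements per year of follow-up.
#' @param dropout_rate Loss-to-follow-up hazard per year.
#' @param entry_year_range Calendar years of the entry window.
#' @param age_range_years Eligible age range at entry.
#' @param frailty_dropout If `TRUE`, the dropout hazard is multiplied by
#'   `exp(frailty_dropout_slope * U)`, making censoring informative.
#' @param frailty_dropout_slope Log-hazard slope of dropout on frailty.
#' @param comorb_base,comorb_u_slope Log-rate intercept and frailty slope of
#'   the Poisson recording count of each designated comorbidity code over the
#'   pre-entry history.
#' @param hist_dx_rate,hist_rx_rate Mean counts of background diagnosis and
#'   medication codes in the pre-entry history.
#' @param hist_u_slope Log-rate slope of the background code counts on the
#'   frailty (frail patients contact care more often).
#' @param prior_hf_prob Probability of a heart-failure code before entry
#'   (triggers the design's exclusion), independent of frailty so that
#'   eligibility does not shift the estimand.
#' @param early_event_prob Probability of a cardiovascular event inside the
#'   12-month exposure period (also an exclusion), independent of frailty.
#' @param noncv_death_rate Non-cardiovascular death hazard per year.
#' @param cv_fatal_frac Fraction of cardiovascular events that are fatal.
#' @param miss_bmi,miss_lipids,miss_smoking,miss_hba1c Marginal
#'   missing-completely-at-random probabilities for the observed covariates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       vocab_size_dx = 60L,
                       vocab_size_rx = 20L,
                       conf_strength = 0.8,
                       sbp_conf_slope = 8,
                       category_effects = c(0, 0.05, 0.09, 0.13, 0.19, 0.28),
                       baseline_logodds = -0.9,
                       covariate_effects = c(age = 0.03, sex_M = 0.25,
                                             smoking_former = 0.12,
                                             smoking_current = 0.35,
                                             bmi = 0.02, af = 0.5, ckd = 0.4),
                       sbp_mean = 138,
                       sbp_between_sd = 16,
                       sbp_noise_sd = 10,
                       measurement_rate = 4,
                       dropout_rate = 0.035,
                       entry_year_range = c(1990L, 2005L),
                       age_range_years = c(50, 90),
                       frailty_dropout = FALSE,
                       frailty_dropout_slope = 0.5,
                       comorb_base = -0.3,
                       comorb_u_slope = 0.7,
                       hist_u_slope = 0.25,
                       hist_dx_rate = 5,
                       hist_rx_rate = 3,
                       prior_hf_prob = 0.03,
                       early_event_prob = 0.02,
                       noncv_death_rate = 0.02,
                       cv_fatal_frac = 0.2,
                       miss_bmi = 0.15,
                       miss_lipids = 0.20,
                       miss_smoking = 0.10,
                       miss_hba1c = 0.451) {
  if (length(n_patients) != 1 || !is.finite(n_patients) || n_patients < 1) {
    abort("`n_patients` must be a positive count.", class = "ehrtmle_config_error")
  }
  if (length(category_effects) != 6) {
    abort("`category_effects` must have length 6.", class = "ehrtmle_config_error")
  }
  if (category_effects[1] != 0) {
    abort("`category_effects[1]` (reference category) must be 0.",
          class = "ehrtmle_config_error")
  }
  if (sbp_noise_sd <= 0 || measurement_rate < 0 || dropout_rate < 0) {
    abort("Rates must be non-negative and `sbp_noise_sd` > 0.",
          class = "ehrtmle_config_error")
  }
  if (vocab_size_dx < length(c(DX_OUTCOME_CODES, DX_FLAG_CODES, DX_COMORB_CODES)) + 1 ||
      vocab_size_rx < length(RX_SPECIAL_CODES) + 1) {
    abort("Vocabulary sizes too small for the designated special codes.",
          class = "ehrtmle_config_error")
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         vocab_size_dx = as.integer(vocab_size_dx),
         vocab_size_rx = as.integer(vocab_size_rx),
         conf_strength = conf_strength, sbp_conf_slope = sbp_conf_slope,
         category_effects = category_effects,
         baseline_logodds = baseline_logodds,
         covariate_effects = covariate_effects,
         sbp_mean = sbp_mean, sbp_between_sd = sbp_between_sd,
         sbp_noise_sd = sbp_noise_sd, measurement_rate = measurement_rate,
         dropout_rate = dropout_rate,
         entry_year_range = as.integer(entry_year_range),
         age_range_years = age_range_years,
         frailty_dropout = isTRUE(frailty_dropout),
         frailty_dropout_slope = frailty_dropout_slope,
         comorb_base = comorb_base, comorb_u_slope = comorb_u_slope,
         hist_u_slope = hist_u_slope,
         hist_dx_rate = hist_dx_rate, hist_rx_rate = hist_rx_rate,
         prior_hf_prob = prior_hf_prob, early_event_prob = early_event_prob,
         noncv_death_rate = noncv_death_rate, cv_fatal_frac = cv_fatal_frac,
         miss_bmi = miss_bmi, miss_lipids = miss_lipids,
         miss_smoking = miss_smoking, miss_hba1c = miss_hba1c),
    class = "sim_config")
}

sim_code_vocab <- function(config) {
  n_bg_dx <- config$vocab_size_dx -
    length(c(DX_OUTCOME_CODES, DX_FLAG_CODES, DX_COMORB_CODES))
  n_bg_rx <- config$vocab_size_rx - length(RX_SPECIAL_CODES)
  list(dx_background = sprintf("dx_b%02d", seq_len(n_bg_dx)),
       rx_background = sprintf("rx_b%02d", seq_len(n_bg_rx)))
}

# Truncated-normal age at entry via inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# Latent covariate/frailty draws plus the 6-column potential-risk matrix.
# Shared between population generation and the counterfactual oracle; all
# draws are vectorized and occur in a fixed order.
draw_latents <- function(config, n) {
  u <- rnorm(n)
  sex <- ifelse(runif(n) < 0.45, "F", "M")
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.61, 0.20, 0.19))
  age_entry <- rtruncnorm(n, 65, 10, config$age_range_years[1],
                          config$age_range_years[2])
  bmi <- rnorm(n, 29 + 0.5 * u, 4)
  hdl <- rnorm(n, 1.25, 0.3)
  total_chol <- rnorm(n, 5.2, 1.0)
  triglycerides <- pmax(rnorm(n, 1.9 + 0.1 * u, 0.8), 0.2)
  af <- runif(n) < expit(-3 + 0.6 * u)
  ckd <- runif(n) < expit(-3 + 0.7 * u)
  hba1c <- rnorm(n, 60 + 1.5 * u, 12)
  diabetes_duration <- pmin(rexp(n, 1 / 6), 40)
  mu_sbp <- config$sbp_mean + config$sbp_conf_slope * u +
    rnorm(n, 0, config$sbp_between_sd)
  mu_sbp <- clip(mu_sbp, 55, 295)

  ce <- config$covariate_effects
  eff <- function(nm) if (nm %in% names(ce)) ce[[nm]] else 0
  lp <- config$baseline_logodds + config$conf_strength * u +
    eff("age") * (age_entry - 65) +
    eff("sex_M") * (sex == "M") +
    eff("smoking_former") * (smoking == "former") +
    eff("smoking_current") * (smoking == "current") +
    eff("bmi") * (bmi - 29) +
    eff("af") * af + eff("ckd") * ckd
  risks <- vapply(config$category_effects,
                  function(b) expit(lp + b), numeric(n))
  if (n == 1) risks <- matrix(risks, nrow = 1)
  colnames(risks) <- paste0("risk_cat", 0:5)

  tibble::tibble(u = u, sex = sex, smoking = smoking, age_entry = age_entry,
                 bmi = bmi, hdl = hdl, total_chol = total_chol,
                 triglycerides = triglycerides, af = af, ckd = ckd,
                 hba1c = hba1c, diabetes_duration = diabetes_duration,
                 mu_sbp = mu_sbp) |>
    dplyr::bind_cols(tibble::as_tibble(risks))
}

#' Generate a synthetic EHR population
#'
#' Simulates `config$n_patients` patients: demographics, a latent frailty,
#' pre-entry coded diagnosis/medication histories (with frailty-linked
#' comorbidity codes), repeated noisy SBP measurements over a 10-year window
#' starting at the first measurement, cardiovascular events in months 12-120
#' drawn from the stored potential risks, exposure-period events, prior heart
#' failure, dropout and non-cardiovascular death. Potential outcomes are
#' generated *before* exposure realization, so exchangeability holds by
#' construction.
#'
#' @param config A [sim_config()].
#' @return A list of class `ehr_population` with tibbles `patients`
#'   (one row per patient, including synthetic-only columns `latent_u`,
#'   `latent_sbp_mean`, `latent_cat`, `latent_y` — the realized potential
#'   outcome before any censoring — and `risk_cat0`..`risk_cat5`), `events`
#'   (pid, day, code, modality) and `measurements` (pid, day, sbp), plus the
#'   `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(config) {
  n <- config$n_patients
  vocab <- sim_code_vocab(config)
  lat <- draw_latents(config, n)
  pid <- sprintf("p%06d", seq_len(n))

  # entry day = day of the first SBP measurement; always inside the window
  entry_year <- sample(seq(config$entry_year_range[1], config$entry_year_range[2]),
                       n, replace = TRUE)
  t0 <- floor((entry_year - 1990) * DAYS_PER_YEAR) + sample.int(365, n, replace = TRUE) - 1L
  birth_day <- t0 - round(lat$age_entry * DAYS_PER_YEAR)

  # exposure realization: the *generating mean* determines the latent category
  latent_cat <- categorize_sbp(clip(lat$mu_sbp, 50, 300))
  risk_mat <- as.matrix(lat[paste0("risk_cat", 0:5)])
  y_u <- runif(n)
  y <- y_u < risk_mat[cbind(seq_len(n), latent_cat + 1L)]

  # main cardiovascular event in (t0+365, t0+3650]; fatal with prob cv_fatal_frac
  ev_day <- ifelse(y, t0 + EXPOSURE_PERIOD_DAYS +
                     ceiling(runif(n) * (FOLLOWUP_END_DAY - EXPOSURE_PERIOD_DAYS)),
                   NA_real_)
  ev_type <- sample(DX_OUTCOME_CODES, n, replace = TRUE, prob = c(0.45, 0.30, 0.25))
  ev_fatal <- runif(n) < config$cv_fatal_frac

  # exclusion-generating processes, independent of frailty by design
  early <- runif(n) < config$early_event_prob
  early_day <- t0 + sample.int(EXPOSURE_PERIOD_DAYS, n, replace = TRUE) - 1L
  early_type <- sample(DX_OUTCOME_CODES, n, replace = TRUE)
  prior_hf <- runif(n) < config$prior_hf_prob
  prior_hf_day <- t0 - sample(30:1500, n, replace = TRUE)

  # dropout and non-CV death
  drop_rate <- config$dropout_rate *
    if (config$frailty_dropout) exp(config$frailty_dropout_slope * lat$u) else 1
  censor_day <- t0 + round(rexp(n, pmax(drop_rate, 1e-12)) * DAYS_PER_YEAR)
  censor_day[censor_day > t0 + FOLLOWUP_END_DAY | config$dropout_rate == 0] <- NA_real_
  noncv_day <- t0 + round(rexp(n, pmax(config$noncv_death_rate, 1e-12)) * DAYS_PER_YEAR)
  noncv_day[noncv_day > t0 + FOLLOWUP_END_DAY | config$noncv_death_rate == 0] <- NA_real_

  death_day <- rep(NA_real_, n)
  death_cause <- rep(NA_character_, n)
  cv_death <- !is.na(ev_day) & ev_fatal &
    (is.na(noncv_day) | ev_day <= noncv_day)
  death_day[cv_death] <- ev_day[cv_death]
  death_cause[cv_death] <- "cvd"
  other_death <- !is.na(noncv_day) & !cv_death
  death_day[other_death] <- noncv_day[other_death]
  death_cause[other_death] <- "other"

  end_day <- pmin(death_day, censor_day, t0 + FOLLOWUP_END_DAY, na.rm = TRUE)
  ev_day[!is.na(ev_day) & ev_day > end_day] <- NA_real_  # unobserved events

  # SBP measurements: one at entry plus a Poisson stream over follow-up
  k <- rpois(n, config$measurement_rate * 10)
  mpid <- c(pid, rep(pid, k))
  mday <- c(t0, rep(t0, k) + ceiling(runif(sum(k)) * FOLLOWUP_END_DAY))
  mval <- rnorm(length(mpid),
                c(lat$mu_sbp, rep(lat$mu_sbp, k)), config$sbp_noise_sd)
  mend <- c(end_day, rep(end_day, k))
  keep <- mday <= mend
  measurements <- tibble::tibble(pid = mpid[keep], day = mday[keep],
                                 sbp = round(mval[keep], 1)) |>
    dplyr::arrange(.data$pid, .data$day)

  # coded history: background codes + frailty-linked comorbidity codes + flags
  ev_list <- list()
  hist_mult <- exp(config$hist_u_slope * lat$u)
  n_dx <- rpois(n, config$hist_dx_rate * hist_mult)
  ev_list$bg_dx <- tibble::tibble(
    pid = rep(pid, n_dx),
    day = rep(t0, n_dx) - ceiling(runif(sum(n_dx)) * 1825),
    code = sample(vocab$dx_background, sum(n_dx), replace = TRUE),
    modality = "dx")
  n_rx <- rpois(n, config$hist_rx_rate * hist_mult)
  ev_list$bg_rx <- tibble::tibble(
    pid = rep(pid, n_rx),
    day = rep(t0, n_rx) - ceiling(runif(sum(n_rx)) * 1825),
    code = sample(vocab$rx_background, sum(n_rx), replace = TRUE),
    modality = "rx")
  # frailty-linked comorbidity recordings: each designated code is recorded a
  # Poisson number of times with log-rate linear in the frailty, so the total
  # count over the history is an informative (noisy) frailty proxy
  com_rate <- exp(config$comorb_base + config$comorb_u_slope * lat$u)
  for (cc in DX_COMORB_CODES) {
    k_com <- rpois(n, com_rate)
    ev_list[[cc]] <- tibble::tibble(
      pid = rep(pid, k_com),
      day = rep(t0, k_com) - ceiling(runif(sum(k_com)) * 1825),
      code = cc, modality = "dx")
  }
  ev_list$af <- tibble::tibble(pid = pid[lat$af],
                               day = t0[lat$af] - ceiling(runif(sum(lat$af)) * 1825),
                               code = "dx_af", modality = "dx")
  ev_list$ckd <- tibble::tibble(pid = pid[lat$ckd],
                                day = t0[lat$ckd] - ceiling(runif(sum(lat$ckd)) * 1825),
                                code = "dx_ckd", modality = "dx")

  # treatment codes: baseline antihypertensive use rises with the SBP mean
  p_aht <- expit(0.04 * (lat$mu_sbp - 150))
  aht_base <- runif(n) < p_aht
  ev_list$aht_base <- tibble::tibble(
    pid = pid[aht_base], day = t0[aht_base] - sample.int(365, sum(aht_base), replace = TRUE),
    code = "rx_antihtn", modality = "rx")
  aht_after <- (aht_base & runif(n) < 0.8) | (!aht_base & runif(n) < 0.1 * p_aht)
  ev_list$aht_after <- tibble::tibble(
    pid = pid[aht_after],
    day = t0[aht_after] + sample.int(FOLLOWUP_END_DAY, sum(aht_after), replace = TRUE),
    code = "rx_antihtn", modality = "rx")
  insulin <- runif(n) < expit(-1.1 + 0.2 * lat$u)
  ev_list$insulin <- tibble::tibble(
    pid = pid[insulin], day = t0[insulin] - sample.int(365, sum(insulin), replace = TRUE),
    code = "rx_insulin", modality = "rx")

  # outcome / exclusion codes
  ev_list$prior_hf <- tibble::tibble(pid = pid[prior_hf], day = prior_hf_day[prior_hf],
                                     code = "dx_hf", modality = "dx")
  ev_list$early <- tibble::tibble(pid = pid[early], day = early_day[early],
                                  code = early_type[early], modality = "dx")
  has_ev <- !is.na(ev_day)
  ev_list$main <- tibble::tibble(pid = pid[has_ev], day = ev_day[has_ev],
                                 code = ev_type[has_ev], modality = "dx")

  events <- dplyr::bind_rows(ev_list)
  end_by_pid <- setNames(end_day, pid)
  birth_by_pid <- setNames(birth_day, pid)
  events$day <- pmax(events$day, birth_by_pid[events$pid] + 1)
  events <- events[events$day <= end_by_pid[events$pid], ] |>
    dplyr::arrange(.data$pid, .data$day, .data$code)

  cv_codes_day <- events |>
    dplyr::filter(.data$code %in% DX_OUTCOME_CODES) |>
    dplyr::group_by(.data$pid) |>
    dplyr::summarise(first = min(.data$day), .groups = "drop")
  cv_event_day <- setNames(rep(NA_real_, n), pid)
  cv_event_day[cv_codes_day$pid] <- cv_codes_day$first

  # observed-covariate missingness (MCAR)
  mask <- function(x, p) replace(x, runif(n) < p, NA)
  patients <- tibble::tibble(
    pid = pid, sex = lat$sex, birth_day = birth_day,
    smoking = mask(lat$smoking, config$miss_smoking),
    censor_day = censor_day, death_day = death_day, death_cause = death_cause,
    bmi = round(mask(lat$bmi, config$miss_bmi), 2),
    hdl = round(mask(lat$hdl, config$miss_lipids), 3),
    total_chol = round(mask(lat$total_chol, config$miss_lipids), 3),
    triglycerides = round(mask(lat$triglycerides, config$miss_lipids), 3),
    hba1c = round(mask(lat$hba1c, config$miss_hba1c), 1),
    diabetes_duration = round(lat$diabetes_duration, 2),
    cv_event_day = unname(cv_event_day),
    latent_u = round(lat$u, 6), latent_sbp_mean = round(lat$mu_sbp, 4),
    latent_cat = latent_cat, latent_y = as.integer(y))
  patients <- dplyr::bind_cols(patients,
                               round(lat[paste0("risk_cat", 0:5)], 9))

  structure(list(patients = patients, events = events,
                 measurements = measurements, config = config),
            class = "ehr_population")
}

#' @exportS3Method base::print
print.ehr_population <- function(x, ...) {
  cat(sprintf("<ehr_population> %d patients, %d coded events, %d SBP measurements\n",
              nrow(x$patients), nrow(x$events), nrow(x$measurements)))
  invisible(x)
}

#' Monte-Carlo oracle for the true marginal risk ratio
#'
#' Draws `n_mc` fresh patients from the configured data-generating process and
#' averages their stored potential risks to obtain the true marginal risk
#' under a given exposure category, returning the ratio to the reference
#' category (<120 mm Hg) together with a delta-method standard error.
#'
#' @param config A [sim_config()].
#' @param category Exposure category 0..5 (0 is the reference).
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Seed for the fresh draws.
#' @return A list with `rr`, `se` (SE of the ratio; 0 for the reference),
#'   `psi` (marginal risk in `category`), `psi_ref`, and `n_mc`.
#' @export
oracle_true_rr <- function(config, category, n_mc = 1e5, seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"))
  if (length(category) != 1 || !(category %in% 0:5)) {
    abort("`category` must be a single value in 0..5.",
          class = "ehrtmle_config_error")
  }
  if (n_mc < 1) abort("`n_mc` must be >= 1.", class = "ehrtmle_config_error")
  lat <- with_seed(seed, draw_latents(config, n_mc))
  ra <- lat[[paste0("risk_cat", category)]]
  r0 <- lat[["risk_cat0"]]
  psi_a <- mean(ra)
  psi_0 <- mean(r0)
  if (category == 0) {
    return(list(rr = 1.0, se = 0.0, psi = psi_a, psi_ref = psi_0, n_mc = n_mc))
  }
  # delta method on the ratio of means of the paired potential risks
  ic <- ra / psi_0 - psi_a * r0 / psi_0^2
  list(rr = psi_a / psi_0, se = sd(ic) / sqrt(n_mc),
       psi = psi_a, psi_ref = psi_0, n_mc = n_mc)
}

#' Frailty-confounded scenario with a monotone true risk gradient
#'
#' Preset configuration for the reverse-causation demonstration: a latent
#' frailty *lowers* the patient's SBP while strongly raising outcome risk, so
#' the lowest SBP categories are enriched in frail patients and crude (or
#' weakly adjusted) contrasts exhibit an interior risk minimum above the
#' reference category, while the true category effects rise monotonically.
#' The frailty leaves a footprint in the coded history through the designated
#' comorbidity codes, which history-aware nuisance models can exploit.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_jshape <- function(n_patients, seed = 1L, ...) {
  args <- list(n_patients = n_patients, seed = seed,
               conf_strength = 1.0, sbp_conf_slope = -14,
               sbp_between_sd = 16,
               category_effects = c(0, 0.2, 0.5, 0.9, 1.5, 2.3),
               baseline_logodds = -1.8,
               comorb_u_slope = 1.0, hist_u_slope = 0.4)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
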