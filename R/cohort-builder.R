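# Study design: entry at the first qualifying SBP measurement, 12-month
# baseline exposure averaging, six SBP categories, exclusions, composite
# outcome ascertainment over months 12-120, stratified fold assignment, and
# the sensitivity-analysis variants.

#' Study design configuration
#'
#' Encodes the cohort construction rules: entry window (calendar years of the
#' first qualifying blood-pressure measurement), eligible age range, SBP
#' plausibility bounds, the 12-month exposure period, the months 12-120
#' follow-up window (in days, with 12 months = 365 days), and the exposure
#' category edges.
#'
#' @param entry_years Calendar-year window for study entry.
#' @param age_range Eligible age range (years, inclusive) at entry.
#' @param sbp_valid Plausibility bounds; values strictly outside are dropped.
#' @param exposure_period_days Length of the baseline exposure period.
#' @param followup_start_day,followup_end_day Follow-up window relative to
#'   entry; events in `(start, end]` count as outcomes.
#' @param category_edges Interior SBP category edges (mm Hg); bins are
#'   half-open `[edge, next_edge)` with `<120` the reference and `>=160` the
#'   top category.
#' @param composite_codes Diagnosis codes forming the composite
#'   cardiovascular outcome (cardiovascular death is always included via the
#'   death-cause record).
#' @param hf_codes Codes identifying heart failure for the prior-HF exclusion.
#' @param secondary_outcomes Named list of component code sets.
#' @param antihypertensive_codes,insulin_codes Medication codes used to derive
#'   baseline-treatment flags.
#' @param af_codes,ckd_codes Codes for the atrial-fibrillation and
#'   chronic-kidney-disease baseline flags.
#' @param comorbidity_codes History codes summarised into `comorb_count`.
#' @param n_folds Number of cross-fitting folds.
#' @return A list of class `study_config`.
#' @export
study_config <- function(entry_years = c(1990L, 2005L),
                         age_range = c(50, 90),
                         sbp_valid = c(50, 300),
                         exposure_period_days = 365L,
                         followup_start_day = 365L,
                         followup_end_day = 3650L,
                         category_edges = c(120, 130, 140, 150, 160),
                         composite_codes = c("dx_ihd", "dx_hf", "dx_stroke"),
                         hf_codes = "dx_hf",
                         secondary_outcomes = list(ihd = "dx_ihd", hf = "dx_hf",
                                                   stroke = "dx_stroke"),
                         antihypertensive_codes = "rx_antihtn",
                         insulin_codes = "rx_insulin",
                         af_codes = "dx_af",
                         ckd_codes = "dx_ckd",
                         comorbidity_codes = paste0("dx_comorb", 1:5),
                         n_folds = 5L) {
  if (any(diff(category_edges) <= 0)) {
    abort("`category_edges` must be strictly increasing.",
          class = "ehrtmle_config_error")
  }
  if (followup_start_day >= followup_end_day) {
    abort("`followup_start_day` must be < `followup_end_day`.",
          class = "ehrtmle_config_error")
  }
  structure(list(entry_years = as.integer(entry_years), age_range = age_range,
                 sbp_valid = sbp_valid,
                 exposure_period_days = as.integer(exposure_period_days),
                 followup_start_day = as.integer(followup_start_day),
                 followup_end_day = as.integer(followup_end_day),
                 category_edges = category_edges,
                 composite_codes = composite_codes, hf_codes = hf_codes,
                 secondary_outcomes = secondary_outcomes,
                 antihypertensive_codes = antihypertensive_codes,
                 insulin_codes = insulin_codes,
                 af_codes = af_codes, ckd_codes = ckd_codes,
                 comorbidity_codes = comorbidity_codes,
                 n_folds = as.integer(n_folds)),
            class = "study_config")
}

entry_window_days <- function(config) {
  c(floor((config$entry_years[1] - 1990) * DAYS_PER_YEAR),
    floor((config$entry_years[2] + 1 - 1990) * DAYS_PER_YEAR))
}

#' Find the study entry day for one patient
#'
#' Study entry is the day of the first SBP measurement that falls inside the
#' calendar entry window with the patient aged inside the eligible range on
#' that day; `NA` if no measurement qualifies.
#'
#' @param patient A per-patient list with `birth_day` and a `measurements`
#'   tibble (`day`, `sbp`), as returned by [patient_record()].
#' @param config A [study_config()].
#' @return Entry day index, or `NA` if the patient never qualifies.
#' @export
find_study_entry <- function(patient, config = study_config()) {
  m <- patient$measurements
  if (is.null(m) || nrow(m) == 0) return(NA_real_)
  win <- entry_window_days(config)
  age <- (m$day - patient$birth_day) / DAYS_PER_YEAR
  ok <- m$day >= win[1] & m$day < win[2] &
    age >= config$age_range[1] & age <= config$age_range[2]
  if (!any(ok)) return(NA_real_)
  min(m$day[ok])
}

#' Drop physiologically implausible SBP values
#'
#' Retains measurements with `sbp_valid[1] <= value <= sbp_valid[2]`
#' (defaults 50 and 300 mm Hg; only values strictly outside the bounds are
#' excluded), preserving order.
#'
#' @param measurements Tibble with columns `day` and `sbp` (and optionally
#'   `pid`, used in error messages).
#' @param config A [study_config()].
#' @return The filtered tibble.
#' @export
clean_sbp <- function(measurements, config = study_config()) {
  if (nrow(measurements) == 0) return(measurements)
  if (!is.numeric(measurements$sbp)) {
    bad <- which(is.na(suppressWarnings(as.numeric(measurements$sbp))))[1]
    pid <- if ("pid" %in% names(measurements)) measurements$pid[bad] else "<unknown>"
    abort(sprintf("Non-numeric SBP value for patient %s at row %d.", pid, bad),
          class = "ehrtmle_data_error")
  }
  measurements[measurements$sbp >= config$sbp_valid[1] &
                 measurements$sbp <= config$sbp_valid[2], , drop = FALSE]
}

#' Baseline exposure: mean SBP over the first 12 months after entry
#'
#' Arithmetic mean of the cleaned SBP values measured in
#' `[entry_day, entry_day + exposure_period_days)` (half-open window).
#'
#' @inheritParams find_study_entry
#' @param entry_day Entry day from [find_study_entry()].
#' @return Mean SBP in mm Hg, or `NA` if no valid value lies in the window.
#' @export
compute_baseline_exposure <- function(patient, entry_day, config = study_config()) {
  m <- clean_sbp(patient$measurements, config)
  v <- m$sbp[m$day >= entry_day & m$day < entry_day + config$exposure_period_days]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Assign the SBP exposure category
#'
#' Half-open bins on the interior edges: `<120` maps to 0 (reference),
#' `[120,130)` to 1, ..., `>=160` to 5. Vectorized.
#'
#' @param mean_sbp Baseline mean SBP values, each inside the plausibility
#'   bounds (cleaning must precede categorization).
#' @param config A [study_config()].
#' @return Integer categories in 0..5.
#' @export
categorize_sbp <- function(mean_sbp, config = study_config()) {
  if (any(mean_sbp < config$sbp_valid[1] | mean_sbp > config$sbp_valid[2],
          na.rm = TRUE)) {
    abort("`mean_sbp` outside the plausibility bounds; clean values first.",
          class = "ehrtmle_logic_error")
  }
  findInterval(mean_sbp, config$category_edges)
}

first_code_day <- function(events, codes, lo = -Inf, hi = Inf,
                           lo_open = FALSE, hi_open = FALSE) {
  d <- events$day[events$code %in% codes]
  d <- d[(if (lo_open) d > lo else d >= lo) & (if (hi_open) d < hi else d <= hi)]
  if (length(d) == 0) NA_real_ else min(d)
}

# First composite cardiovascular event day within [lo, hi] (lo exclusive if
# lo_open): the earliest composite diagnosis code or cardiovascular death.
composite_event_day <- function(patient, config, lo, hi, lo_open = FALSE) {
  d <- first_code_day(patient$events, config$composite_codes, lo, hi,
                      lo_open = lo_open)
  if (!is.null(patient$death_day) && !is.na(patient$death_day) &&
      identical(patient$death_cause, "cvd")) {
    dd <- patient$death_day
    if ((if (lo_open) dd > lo else dd >= lo) && dd <= hi) d <- min(d, dd, na.rm = TRUE)
  }
  d
}

#' Apply the design's exclusion rules to one patient
#'
#' Rules, in precedence order: (1) a heart-failure code before entry;
#' (2) a composite cardiovascular event during the exposure period
#' `[entry, entry + 365]`; (3) censoring or death during the exposure period.
#'
#' @inheritParams compute_baseline_exposure
#' @return A list with `eligible` (flag) and `reason` (`NA`, `"prior_hf"`,
#'   `"event_in_exposure_period"` or `"dropout_in_exposure_period"`).
#' @export
apply_exclusions <- function(patient, entry_day, config = study_config()) {
  hf <- first_code_day(patient$events, config$hf_codes, -Inf, entry_day,
                       hi_open = TRUE)
  if (!is.na(hf)) {
    return(list(eligible = FALSE, reason = "prior_hf"))
  }
  hi <- entry_day + config$exposure_period_days
  ev <- composite_event_day(patient, config, entry_day, hi)
  if (!is.na(ev)) {
    return(list(eligible = FALSE, reason = "event_in_exposure_period"))
  }
  leave <- suppressWarnings(min(patient$censor_day, patient$death_day, na.rm = TRUE))
  if (is.finite(leave) && leave >= entry_day && leave <= hi) {
    return(list(eligible = FALSE, reason = "dropout_in_exposure_period"))
  }
  list(eligible = TRUE, reason = NA_character_)
}

#' Ascertain the binary outcome over months 12-120
#'
#' Outcome is 1 iff the first event in `code_set` (or cardiovascular death)
#' falls in `(entry + followup_start_day, entry + followup_end_day]`.
#' Patients leaving the study before the window closes without an event get
#' outcome 0 with their censoring day recorded (the binary-outcome
#' framework's acknowledged limitation).
#'
#' @inheritParams compute_baseline_exposure
#' @param code_set Diagnosis codes defining the outcome; defaults to the
#'   composite set. Pass a component set for secondary outcomes.
#' @return A list with `outcome` (0/1), `event_day` and `censor_day`.
#' @export
ascertain_outcome <- function(patient, entry_day, config = study_config(),
                              code_set = NULL) {
  lo <- entry_day + config$followup_start_day
  hi <- entry_day + config$followup_end_day
  cfg <- config
  if (!is.null(code_set)) cfg$composite_codes <- code_set
  ev <- composite_event_day(patient, cfg, lo, hi, lo_open = TRUE)
  if (!is.na(ev)) {
    return(list(outcome = 1L, event_day = ev, censor_day = NA_real_))
  }
  leave <- suppressWarnings(min(patient$censor_day, patient$death_day, na.rm = TRUE))
  censor <- if (is.finite(leave) && leave <= hi) leave else NA_real_
  list(outcome = 0L, event_day = NA_real_, censor_day = censor)
}

#' Extract one patient's record from a population
#'
#' @param population An `ehr_population`.
#' @param pid Patient identifier.
#' @return A list with the patient's row fields plus `events` and
#'   `measurements` tibbles.
#' @export
patient_record <- function(population, pid) {
  row <- population$patients[population$patients$pid == pid, ]
  if (nrow(row) == 0) abort(sprintf("Unknown pid %s.", pid),
                            class = "ehrtmle_data_error")
  rec <- as.list(row)
  rec$events <- population$events[population$events$pid == pid, ]
  rec$measurements <- population$measurements[population$measurements$pid == pid, ]
  rec
}

# Stratified fold assignment: within each exposure category, a seeded random
# permutation is dealt round-robin, so per-category fold counts differ by <= 1.
assign_folds <- function(categories, n_folds, seed) {
  folds <- integer(length(categories))
  with_seed(seed, {
    for (cat in sort(unique(categories))) {
      idx <- which(categories == cat)
      folds[sample(idx)] <- (seq_along(idx) - 1L) %% n_folds
    }
  })
  folds
}

#' Build the analysis cohort
#'
#' Applies, in order: entry resolution, prior-heart-failure exclusion,
#' exposure-period event/dropout exclusions, SBP cleaning and 12-month
#' baseline averaging, exposure categorization, outcome ascertainment, and
#' stratified fold assignment. Returns one analysis-ready row per retained
#' patient plus an exact patient-flow accounting.
#'
#' @param population An `ehr_population` (or an equivalent list of `patients`,
#'   `events`, `measurements` tibbles).
#' @param config A [study_config()].
#' @param fold_seed Seed for the stratified fold permutation.
#' @param include_exposure_period_events If `TRUE`, exposure-period event and
#'   dropout exclusions are skipped and the outcome window opens at entry
#'   (the design's "include first-12-month events" sensitivity variant).
#' @return A list with `cohort` (tibble, one row per patient) and `flow`
#'   (class `flow_counts`).
#' @export
build_cohort <- function(population, config = study_config(), fold_seed = 1L,
                         include_exposure_period_events = FALSE) {
  pts <- population$patients
  n <- nrow(pts)
  ev_split <- split(seq_len(nrow(population$events)), population$events$pid)
  ms_split <- split(seq_len(nrow(population$measurements)), population$measurements$pid)
  win <- entry_window_days(config)

  reasons <- character(n)
  num0 <- rep(NA_real_, n); int0 <- rep(NA_integer_, n); lg0 <- rep(NA, n)
  acc <- list(entry_day = num0, mean_sbp = num0, outcome = int0,
              event_day = num0, censor_day = num0,
              antihypertensive_baseline = lg0,
              antihypertensive_after_entry = lg0, insulin_baseline = lg0,
              af = lg0, ckd = lg0, comorb_count = int0,
              n_dx_prior = int0, n_rx_prior = int0)
  for (i in seq_len(n)) {
    p <- list(pid = pts$pid[i], birth_day = pts$birth_day[i],
              censor_day = pts$censor_day[i], death_day = pts$death_day[i],
              death_cause = pts$death_cause[i])
    p$events <- population$events[ev_split[[p$pid]] %||% integer(), ]
    p$measurements <- population$measurements[ms_split[[p$pid]] %||% integer(), ]
    entry <- find_study_entry(p, config)
    if (is.na(entry)) { reasons[i] <- "no_entry"; next }
    if (include_exposure_period_events) {
      hf <- first_code_day(p$events, config$hf_codes, -Inf, entry, hi_open = TRUE)
      excl <- list(eligible = is.na(hf),
                   reason = if (is.na(hf)) NA_character_ else "prior_hf")
    } else {
      excl <- apply_exclusions(p, entry, config)
    }
    if (!excl$eligible) {
      reasons[i] <- if (excl$reason == "prior_hf") "prior_hf" else
        "event_or_dropout_in_exposure_period"
      next
    }
    mean_sbp <- compute_baseline_exposure(p, entry, config)
    if (is.na(mean_sbp)) { reasons[i] <- "no_valid_sbp"; next }
    cfg_out <- config
    if (include_exposure_period_events) cfg_out$followup_start_day <- 0L
    out <- ascertain_outcome(p, entry, cfg_out)
    ev <- p$events
    pre <- ev$day <= entry
    reasons[i] <- "final"
    acc$entry_day[i] <- entry
    acc$mean_sbp[i] <- mean_sbp
    acc$outcome[i] <- out$outcome
    acc$event_day[i] <- out$event_day
    acc$censor_day[i] <- out$censor_day
    aht <- ev$code %in% config$antihypertensive_codes
    acc$antihypertensive_baseline[i] <- any(aht & pre)
    acc$antihypertensive_after_entry[i] <- any(aht & !pre)
    acc$insulin_baseline[i] <- any(ev$code %in% config$insulin_codes & pre)
    acc$af[i] <- any(ev$code %in% config$af_codes & pre)
    acc$ckd[i] <- any(ev$code %in% config$ckd_codes & pre)
    acc$comorb_count[i] <- sum(ev$code %in% config$comorbidity_codes & pre)
    acc$n_dx_prior[i] <- sum(pre & ev$modality == "dx")
    acc$n_rx_prior[i] <- sum(pre & ev$modality == "rx")
  }

  keep <- reasons == "final"
  cohort <- tibble::tibble(
    pid = pts$pid[keep],
    entry_day = acc$entry_day[keep],
    exposure_cat = categorize_sbp(acc$mean_sbp[keep], config),
    mean_sbp = acc$mean_sbp[keep],
    age_at_entry = (acc$entry_day[keep] - pts$birth_day[keep]) / DAYS_PER_YEAR,
    sex = pts$sex[keep], smoking = pts$smoking[keep],
    bmi = pts$bmi[keep], hdl = pts$hdl[keep],
    total_chol = pts$total_chol[keep],
    triglycerides = pts$triglycerides[keep],
    antihypertensive_baseline = acc$antihypertensive_baseline[keep],
    antihypertensive_after_entry = acc$antihypertensive_after_entry[keep],
    insulin_baseline = acc$insulin_baseline[keep],
    hba1c_mean_12m = pts$hba1c[keep],
    diabetes_duration = pts$diabetes_duration[keep],
    af = acc$af[keep], ckd = acc$ckd[keep],
    comorb_count = acc$comorb_count[keep],
    n_dx_prior = acc$n_dx_prior[keep], n_rx_prior = acc$n_rx_prior[keep],
    outcome = acc$outcome[keep],
    event_day = acc$event_day[keep], censor_day = acc$censor_day[keep])
  if (nrow(cohort) == 0) {
    abort("No patients remain after applying the study design.",
          class = "ehrtmle_empty_cohort")
  }
  cohort$fold <- assign_folds(cohort$exposure_cat, config$n_folds, fold_seed)

  per_cat <- cohort |>
    dplyr::group_by(category = .data$exposure_cat) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$outcome), .groups = "drop")
  flow <- structure(list(
    n_input = n,
    n_no_entry = sum(reasons == "no_entry"),
    n_prior_hf = sum(reasons == "prior_hf"),
    n_event_or_dropout_in_exposure_period =
      sum(reasons == "event_or_dropout_in_exposure_period"),
    n_no_valid_sbp = sum(reasons == "no_valid_sbp"),
    n_final = nrow(cohort),
    per_category = per_cat), class = "flow_counts")
  stopifnot(flow$n_input == flow$n_final + flow$n_no_entry + flow$n_prior_hf +
              flow$n_event_or_dropout_in_exposure_period + flow$n_no_valid_sbp)
  list(cohort = cohort, flow = flow)
}

#' @exportS3Method base::print
print.flow_counts <- function(x, ...) {
  cat(sprintf(paste0("<flow_counts> input %d | no entry %d | prior HF %d | ",
                     "exposure-period event/dropout %d | no valid SBP %d | final %d\n"),
              x$n_input, x$n_no_entry, x$n_prior_hf,
              x$n_event_or_dropout_in_exposure_period, x$n_no_valid_sbp, x$n_final))
  invisible(x)
}

SENSITIVITY_VARIANTS <- c("sex_F", "sex_M", "age_le_75", "age_gt_75",
                          "no_antihypertensives_after_entry",
                          "strat_baseline_antihypertensive_yes",
                          "strat_baseline_antihypertensive_no",
                          "drop_events_first_12m_followup",
                          "drop_events_first_24m_followup",
                          "include_exposure_period_events")

#' Apply a sensitivity-analysis variant
#'
#' Filters (or rebuilds) the cohort for one of the design's sensitivity
#' analyses: sex and age strata, exclusion of antihypertensive users after
#' entry, strata of baseline antihypertensive use, exclusion of events in the
#' first 12 or 24 months of follow-up, and re-inclusion of patients with
#' exposure-period events (which rebuilds the cohort from the pre-exclusion
#' pool and therefore needs `population`).
#'
#' @param cohort A cohort tibble from [build_cohort()].
#' @param variant One of `sex_F`, `sex_M`, `age_le_75`, `age_gt_75`,
#'   `no_antihypertensives_after_entry`,
#'   `strat_baseline_antihypertensive_yes`/`_no`,
#'   `drop_events_first_12m_followup`, `drop_events_first_24m_followup`,
#'   `include_exposure_period_events`. Colons may be used in place of
#'   underscores after the stratum prefix (e.g. `"sex:F"`).
#' @param population,config,fold_seed Required only for
#'   `include_exposure_period_events`.
#' @return The filtered (or rebuilt) cohort tibble.
#' @export
apply_sensitivity_filter <- function(cohort, variant, population = NULL,
                                     config = study_config(), fold_seed = 1L) {
  variant <- gsub(":", "_", variant, fixed = TRUE)
  if (!variant %in% SENSITIVITY_VARIANTS) {
    abort(sprintf("Unknown sensitivity variant '%s'.", variant),
          class = "ehrtmle_config_error")
  }
  switch(variant,
    sex_F = dplyr::filter(cohort, .data$sex == "F"),
    sex_M = dplyr::filter(cohort, .data$sex == "M"),
    age_le_75 = dplyr::filter(cohort, .data$age_at_entry <= 75),
    age_gt_75 = dplyr::filter(cohort, .data$age_at_entry > 75),
    no_antihypertensives_after_entry =
      dplyr::filter(cohort, !.data$antihypertensive_after_entry),
    strat_baseline_antihypertensive_yes =
      dplyr::filter(cohort, .data$antihypertensive_baseline),
    strat_baseline_antihypertensive_no =
      dplyr::filter(cohort, !.data$antihypertensive_baseline),
    drop_events_first_12m_followup =
      dplyr::filter(cohort, !(.data$outcome == 1 &
        .data$event_day <= .data$entry_day + config$followup_start_day + 365)),
    drop_events_first_24m_followup =
      dplyr::filter(cohort, !(.data$outcome == 1 &
        .data$event_day <= .data$entry_day + config$followup_start_day + 730)),
    include_exposure_period_events = {
      if (is.null(population)) {
        abort("`include_exposure_period_events` needs the source `population`.",
              class = "ehrtmle_config_error")
      }
      build_cohort(population, config, fold_seed,
                   include_exposure_period_events = TRUE)$cohort
    })
}
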