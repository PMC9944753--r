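test_that("study entry requires the age and calendar windows", {
  # first measurement at age 48 (too young), second at 51 within 1990-2005
  birth <- -17532  # 48 years before day 0
  p <- hand_patient(birth_day = birth,
                    m_days = c(days_at_age(birth, 48.5), days_at_age(birth, 51)),
                    m_vals = c(130, 135))
  expect_equal(find_study_entry(p), days_at_age(birth, 51))

  expect_true(is.na(find_study_entry(hand_patient())))  # no measurements

  # two qualifying measurements on the same day: that day is the single entry
  p2 <- hand_patient(m_days = c(500, 500), m_vals = c(130, 150))
  expect_equal(find_study_entry(p2), 500)
  expect_equal(compute_baseline_exposure(p2, 500), 140)

  # measurement after the calendar window never qualifies
  p3 <- hand_patient(m_days = 7000, m_vals = 130)  # year 2009
  expect_true(is.na(find_study_entry(p3)))
})

test_that("implausible SBP values are dropped, bounds retained", {
  m <- tibble::tibble(day = 1:3, sbp = c(49, 120, 301))
  expect_equal(clean_sbp(m)$sbp, 120)
  m2 <- tibble::tibble(day = 1:2, sbp = c(50, 300))
  expect_equal(clean_sbp(m2)$sbp, c(50, 300))
  expect_equal(nrow(clean_sbp(tibble::tibble(day = numeric(0), sbp = numeric(0)))), 0)
  bad <- tibble::tibble(pid = "x9", day = 1, sbp = "12O")
  expect_error(clean_sbp(bad), regexp = "x9", class = "ehrtmle_data_error")
})

test_that("baseline exposure averages the half-open 12-month window", {
  p <- hand_patient(m_days = c(0, 100, 200, 300), m_vals = c(130, 140, 150, 160))
  expect_equal(compute_baseline_exposure(p, 0), 145)
  p2 <- hand_patient(m_days = 10, m_vals = 118)
  expect_equal(compute_baseline_exposure(p2, 10), 118)
  # day entry+365 is outside the averaging window (half-open)
  p3 <- hand_patient(m_days = c(0, 365), m_vals = c(120, 180))
  expect_equal(compute_baseline_exposure(p3, 0), 120)
  # cleaned-away values never enter the mean
  p4 <- hand_patient(m_days = c(0, 50), m_vals = c(40, 130))
  expect_equal(compute_baseline_exposure(p4, 0), 130)
})

test_that("category bins are half-open and exhaust the plausible range", {
  expect_equal(categorize_sbp(c(119.9, 120, 129.99, 130, 145, 160, 159.999, 300)),
               c(0, 1, 1, 2, 3, 5, 4, 5))
  expect_error(categorize_sbp(40), class = "ehrtmle_logic_error")
  expect_error(categorize_sbp(301), class = "ehrtmle_logic_error")
  # fuzz: every plausible mean lands in exactly one bin consistent with edges
  withr::with_seed(99, {
    v <- runif(2000, 50, 300)
    cat <- categorize_sbp(v)
    edges <- c(50, 120, 130, 140, 150, 160, 300.000001)
    expect_true(all(v >= edges[cat + 1] & v < edges[cat + 2]))
  })
})

test_that("exclusion rules fire in precedence order", {
  hf <- hand_patient(ev_days = 400, ev_codes = "dx_hf",
                     m_days = 500, m_vals = 130)
  expect_equal(apply_exclusions(hf, 500)$reason, "prior_hf")

  stroke200 <- hand_patient(ev_days = 700, ev_codes = "dx_stroke")
  expect_equal(apply_exclusions(stroke200, 500)$reason,
               "event_in_exposure_period")

  stroke400 <- hand_patient(ev_days = 900, ev_codes = "dx_stroke")
  expect_true(apply_exclusions(stroke400, 500)$eligible)

  dropout <- hand_patient(censor_day = 600)
  expect_equal(apply_exclusions(dropout, 500)$reason,
               "dropout_in_exposure_period")

  # prior HF wins over an exposure-period event
  both <- hand_patient(ev_days = c(100, 700), ev_codes = c("dx_hf", "dx_ihd"))
  expect_equal(apply_exclusions(both, 500)$reason, "prior_hf")

  # an event at exactly entry+365 still belongs to the exposure period
  boundary <- hand_patient(ev_days = 865, ev_codes = "dx_ihd")
  expect_equal(apply_exclusions(boundary, 500)$reason,
               "event_in_exposure_period")
})

test_that("outcome ascertainment covers months 12-120 with censoring recorded", {
  entry <- 100
  cv_death <- hand_patient(death_day = entry + 30 * 60, death_cause = "cvd")
  out <- ascertain_outcome(cv_death, entry)
  expect_equal(out$outcome, 1L)
  expect_equal(out$event_day, entry + 1800)

  other_death <- hand_patient(death_day = entry + 30 * 60, death_cause = "other")
  out2 <- ascertain_outcome(other_death, entry)
  expect_equal(out2$outcome, 0L)
  expect_equal(out2$censor_day, entry + 1800)

  # boundary: event at entry+365 is not an outcome; entry+366 is
  expect_equal(ascertain_outcome(hand_patient(ev_days = entry + 365,
                                              ev_codes = "dx_ihd"), entry)$outcome, 0L)
  expect_equal(ascertain_outcome(hand_patient(ev_days = entry + 366,
                                              ev_codes = "dx_ihd"), entry)$outcome, 1L)
  # event after the window closes does not count
  expect_equal(ascertain_outcome(hand_patient(ev_days = entry + 3651,
                                              ev_codes = "dx_ihd"), entry)$outcome, 0L)
  # secondary outcome uses its own code set
  stroke <- hand_patient(ev_days = entry + 600, ev_codes = "dx_stroke")
  expect_equal(ascertain_outcome(stroke, entry, code_set = "dx_ihd")$outcome, 0L)
  expect_equal(ascertain_outcome(stroke, entry, code_set = "dx_stroke")$outcome, 1L)
})

test_that("flow counts balance exactly and record prior-HF exclusions", {
  pop <- shared_pop()
  built <- build_cohort(pop, fold_seed = 2)
  fl <- built$flow
  expect_equal(fl$n_input,
               fl$n_final + fl$n_no_entry + fl$n_prior_hf +
                 fl$n_event_or_dropout_in_exposure_period + fl$n_no_valid_sbp)
  expect_equal(sum(built$flow$per_category$n), nrow(built$cohort))

  # hand-made: 10 patients, 2 with heart failure before entry
  mk <- function(i, hf) {
    list(pid = sprintf("h%02d", i), sex = "F", birth_day = -23741,
         smoking = "never", censor_day = NA_real_, death_day = NA_real_,
         death_cause = NA_character_, bmi = 28, hdl = 1.2, total_chol = 5,
         triglycerides = 1.5, hba1c = 55, diabetes_duration = 5,
         hf = hf)
  }
  pts <- dplyr::bind_rows(lapply(1:10, function(i) {
    r <- mk(i, i <= 2); r$hf <- NULL; tibble::as_tibble(r)
  }))
  events <- tibble::tibble(pid = sprintf("h%02d", 1:2), day = -200,
                           code = "dx_hf", modality = "dx")
  meas <- tibble::tibble(pid = rep(sprintf("h%02d", 1:10), each = 2),
                         day = rep(c(100, 200), 10),
                         sbp = rep(c(132, 138), 10))
  tiny <- list(patients = pts, events = events, measurements = meas)
  out <- build_cohort(tiny, fold_seed = 1)
  expect_equal(out$flow$n_prior_hf, 2)
  expect_equal(out$flow$n_final, 8)
  expect_equal(out$flow$n_input, 10)
})

test_that("flow conservation holds on fuzzed generator settings", {
  for (k in 1:4) {
    cfg <- sim_config(150, seed = 50 + k,
                      dropout_rate = c(0, 0.05, 0.3, 0.1)[k],
                      prior_hf_prob = c(0, 0.2, 0.05, 0.5)[k],
                      early_event_prob = c(0.3, 0, 0.1, 0.05)[k])
    fl <- build_cohort(generate_population(cfg), fold_seed = k)$flow
    expect_equal(fl$n_input,
                 fl$n_final + fl$n_no_entry + fl$n_prior_hf +
                   fl$n_event_or_dropout_in_exposure_period + fl$n_no_valid_sbp)
  }
})

test_that("fold assignment is seeded, stratified and stable", {
  pop <- shared_pop()
  c1 <- build_cohort(pop, fold_seed = 9)$cohort
  c2 <- build_cohort(pop, fold_seed = 9)$cohort
  expect_identical(c1, c2)
  c3 <- build_cohort(pop, fold_seed = 10)$cohort
  expect_false(identical(c1$fold, c3$fold))
  tab <- table(c1$exposure_cat, c1$fold)
  expect_true(all(abs(tab - rowSums(tab) / 5) <= 1))
})

test_that("rebuilding from survivors reproduces identical rows", {
  pop <- shared_pop()
  built <- build_cohort(pop, fold_seed = 4)
  keep <- pop$patients$pid %in% built$cohort$pid
  survivors <- list(patients = pop$patients[keep, ],
                    events = pop$events[pop$events$pid %in% built$cohort$pid, ],
                    measurements = pop$measurements[
                      pop$measurements$pid %in% built$cohort$pid, ])
  rebuilt <- build_cohort(survivors, fold_seed = 4)
  expect_equal(rebuilt$cohort, built$cohort)
  expect_equal(rebuilt$flow$n_final, built$flow$n_final)
})

test_that("empty eligible cohort raises an explicit error", {
  p <- hand_patient(ev_days = -100, ev_codes = "dx_hf",
                    m_days = 100, m_vals = 130)
  tiny <- list(patients = tibble::as_tibble(p[c("pid", "sex", "birth_day",
                                                "smoking", "censor_day",
                                                "death_day", "death_cause")]) |>
                 dplyr::mutate(bmi = 28, hdl = 1.2, total_chol = 5,
                               triglycerides = 1.5, hba1c = 55,
                               diabetes_duration = 3),
               events = p$events, measurements = p$measurements)
  expect_error(build_cohort(tiny), class = "ehrtmle_empty_cohort")
})

test_that("sensitivity variants filter and partition as designed", {
  pop <- shared_pop()
  built <- build_cohort(pop, fold_seed = 6)
  cohort <- built$cohort

  f <- apply_sensitivity_filter(cohort, "sex:F")
  expect_equal(nrow(f), sum(cohort$sex == "F"))
  expect_true(all(f$sex == "F"))

  lo <- apply_sensitivity_filter(cohort, "age_le_75")
  hi <- apply_sensitivity_filter(cohort, "age_gt_75")
  expect_equal(dplyr::bind_rows(lo, hi) |> dplyr::arrange(pid),
               cohort |> dplyr::arrange(pid))

  d12 <- apply_sensitivity_filter(cohort, "drop_events_first_12m_followup")
  expect_false(any(d12$outcome == 1 &
                     d12$event_day <= d12$entry_day + 730, na.rm = TRUE))
  d24 <- apply_sensitivity_filter(cohort, "drop_events_first_24m_followup")
  expect_true(nrow(d24) <= nrow(d12))

  noaht <- apply_sensitivity_filter(cohort, "no_antihypertensives_after_entry")
  expect_false(any(noaht$antihypertensive_after_entry))

  yes <- apply_sensitivity_filter(cohort, "strat_baseline_antihypertensive_yes")
  no <- apply_sensitivity_filter(cohort, "strat_baseline_antihypertensive_no")
  expect_equal(nrow(yes) + nrow(no), nrow(cohort))

  inc <- apply_sensitivity_filter(cohort, "include_exposure_period_events",
                                  population = pop)
  expect_gte(nrow(inc), nrow(cohort))
  expect_error(apply_sensitivity_filter(cohort, "include_exposure_period_events"),
               class = "ehrtmle_config_error")
  expect_error(apply_sensitivity_filter(cohort, "no_such_variant"),
               class = "ehrtmle_config_error")
})
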