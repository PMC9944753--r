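# Hand-built patient records and small shared fixtures.

# One patient as consumed by the per-patient cohort operations.
hand_patient <- function(birth_day = -23741,  # ~65 at day 0
                         m_days = numeric(0), m_vals = numeric(0),
                         ev_days = numeric(0), ev_codes = character(0),
                         censor_day = NA_real_, death_day = NA_real_,
                         death_cause = NA_character_, pid = "hp1",
                         sex = "F", smoking = "never") {
  list(pid = pid, sex = sex, smoking = smoking, birth_day = birth_day,
       censor_day = censor_day, death_day = death_day,
       death_cause = death_cause,
       events = tibble::tibble(pid = pid, day = ev_days, code = ev_codes,
                               modality = rep("dx", length(ev_days))),
       measurements = tibble::tibble(pid = pid, day = m_days, sbp = m_vals))
}

days_at_age <- function(birth_day, age) birth_day + round(age * 365.25)

rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Shared small population: generated once per test session.
shared_pop <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) pop <<- generate_population(sim_config(500, seed = 11))
    pop
  }
})
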