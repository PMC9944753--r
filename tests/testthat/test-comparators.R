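mk_cc_cohort <- function(n, seed, beta_arm = 0.5, beta_x = 0.8,
                         conf = TRUE) {
  # binary confounder `af` raising both exposure and outcome
  withr::with_seed(seed, {
    af <- rbinom(n, 1, 0.4) == 1
    p_arm <- if (conf) plogis(-0.5 + 1.2 * af) else rep(0.45, n)
    arm <- rbinom(n, 1, p_arm)
    y <- rbinom(n, 1, plogis(-1 + beta_arm * arm + beta_x * af))
    tibble::tibble(pid = sprintf("c%05d", seq_len(n)),
                   exposure_cat = ifelse(arm == 1, 3L, 0L),
                   outcome = y, af = af,
                   fold = (seq_len(n) - 1L) %% 5L)
  })
}

test_that("crude risk ratio and its textbook variance", {
  # risks 0.2 vs 0.1 -> RR 2 with the closed-form log-SE
  cohort <- tibble::tibble(
    pid = as.character(1:200),
    exposure_cat = rep(c(5L, 0L), each = 100),
    outcome = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90)),
    fold = 0L)
  est <- crude_rr(cohort, 5)
  expect_equal(est$rr, 2)
  expect_equal(est$log_se, sqrt(1 / 20 - 1 / 100 + 1 / 10 - 1 / 100))
  expect_equal(est$ci_low, exp(log(2) - 1.96 * est$log_se))
  expect_equal(est$events1, 20)

  same <- tibble::tibble(pid = as.character(1:100),
                         exposure_cat = rep(c(1L, 0L), 50),
                         outcome = rep(c(1, 1, 0, 0), 25), fold = 0L)
  expect_equal(crude_rr(same, 1)$rr, 1)

  zero <- dplyr::mutate(same, outcome = ifelse(exposure_cat == 0, 0, outcome))
  expect_error(crude_rr(zero, 1), class = "ehrtmle_estimation_error")
})

test_that("exposure-only standardization reproduces the training-fold crude RR", {
  cohort <- mk_cc_cohort(600, seed = 12)
  est <- adjusted_lr_rr(cohort, 3, exposure_only = TRUE)
  folds <- sort(unique(cohort$fold))
  for (i in seq_along(folds)) {
    tr <- cohort[cohort$fold != folds[i] & cohort$exposure_cat %in% c(0L, 3L), ]
    crude_tr <- mean(tr$outcome[tr$exposure_cat == 3]) /
      mean(tr$outcome[tr$exposure_cat == 0])
    expect_equal(est$fold_rrs[[1]][i], crude_tr, tolerance = 1e-10)
  }
})

test_that("saturated single-confounder standardization matches the 2-cell oracle", {
  cohort <- mk_cc_cohort(800, seed = 13)
  est <- adjusted_lr_rr(cohort, 3, covariates = c("af", "arm:af"))
  folds <- sort(unique(cohort$fold))
  for (i in seq_along(folds)) {
    sub <- cohort[cohort$exposure_cat %in% c(0L, 3L), ]
    sub$arm <- as.integer(sub$exposure_cat == 3L)
    tr <- sub[sub$fold != folds[i], ]
    te <- sub[sub$fold == folds[i], ]
    cell <- function(a, x) mean(tr$outcome[tr$arm == a & tr$af == x])
    w <- mean(te$af)
    psi1 <- w * cell(1, TRUE) + (1 - w) * cell(1, FALSE)
    psi0 <- w * cell(0, TRUE) + (1 - w) * cell(0, FALSE)
    expect_equal(est$fold_rrs[[1]][i], psi1 / psi0, tolerance = 1e-10)
  }
})

test_that("under randomized exposure, adjustment leaves the crude RR unchanged", {
  cohort <- mk_cc_cohort(4000, seed = 14, conf = FALSE)
  adj <- adjusted_lr_rr(cohort, 3, covariates = "af")
  crude <- crude_rr(cohort, 3)
  expect_lt(abs(log(adj$rr) - log(crude$rr)), 0.1)
})

test_that("adjustment removes confounding that the crude estimate absorbs", {
  # averaged over replicates, |adjusted - truth| < |crude - truth|
  truth <- local({
    withr::with_seed(1, {
      af <- rbinom(2e6, 1, 0.4)
      mean(plogis(-1 + 0.5 + 0.8 * af)) / mean(plogis(-1 + 0.8 * af))
    })
  })
  bias_adj <- bias_crude <- numeric(10)
  for (r in 1:10) {
    cohort <- mk_cc_cohort(1500, seed = 100 + r)
    bias_adj[r] <- log(adjusted_lr_rr(cohort, 3, covariates = "af")$rr) - log(truth)
    bias_crude[r] <- log(crude_rr(cohort, 3)$rr) - log(truth)
  }
  expect_lt(abs(mean(bias_adj)), abs(mean(bias_crude)))
})

test_that("Cox comparator: brute-force partial likelihood on a hand dataset", {
  # six subjects, one binary covariate, no ties
  cohort <- tibble::tibble(
    pid = as.character(1:6),
    exposure_cat = c(3L, 0L, 3L, 0L, 3L, 0L),
    entry_day = 0,
    outcome = c(1L, 1L, 0L, 1L, 1L, 0L),
    event_day = 365 + c(300, 500, NA, 900, 1400, NA),
    censor_day = c(NA, NA, 365 + 700, NA, NA, 365 + 1800),
    fold = 0L)
  res <- cox_hazard_check(cohort, 3, exposure_only = TRUE)
  # brute force: enumerate the risk sets of the partial likelihood
  x <- as.integer(cohort$exposure_cat == 3L)
  time <- ifelse(cohort$outcome == 1, cohort$event_day, cohort$censor_day) - 365
  status <- cohort$outcome
  negpl <- function(b) {
    ll <- 0
    for (i in which(status == 1)) {
      rs <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[rs])))
    }
    -ll
  }
  bhat <- optimize(negpl, c(-5, 5), tol = 1e-10)$minimum
  expect_lt(abs(log(res$hr) - bhat), 1e-5)
  expect_lt(abs(negpl(log(res$hr)) - negpl(bhat)), 1e-8)
})

test_that("Cox partial likelihood is invariant to time rescaling", {
  cohort <- mk_cc_cohort(400, seed = 15)
  withr::with_seed(16, {
    cohort$entry_day <- 0
    t_raw <- 365 + ceiling(rexp(400, 1 / 800))
    cohort$event_day <- ifelse(cohort$outcome == 1, pmin(t_raw, 3650), NA)
    cohort$censor_day <- ifelse(cohort$outcome == 1, NA, pmin(t_raw, 3649))
  })
  r1 <- cox_hazard_check(cohort, 3, exposure_only = TRUE)
  doubled <- cohort
  doubled$event_day <- 365 + 2 * (cohort$event_day - 365)
  doubled$censor_day <- 365 + 2 * (cohort$censor_day - 365)
  cfg2 <- study_config(followup_end_day = 7000)
  r2 <- cox_hazard_check(doubled, 3, exposure_only = TRUE, config = cfg2)
  expect_equal(r2$hr, r1$hr, tolerance = 1e-8)
})

test_that("Cox null calibration: CI covers HR 1 in most null replicates", {
  cover <- 0
  for (r in 1:20) {
    cohort <- mk_cc_cohort(300, seed = 300 + r, beta_arm = 0, beta_x = 0,
                           conf = FALSE)
    withr::with_seed(400 + r, {
      cohort$entry_day <- 0
      t_raw <- 365 + ceiling(rexp(300, 1 / 1500))
      cohort$event_day <- ifelse(cohort$outcome == 1, pmin(t_raw, 3650), NA)
      cohort$censor_day <- ifelse(cohort$outcome == 1, NA, pmin(t_raw, 3649))
    })
    res <- cox_hazard_check(cohort, 3, exposure_only = TRUE)
    cover <- cover + (res$ci_low <= 1 && 1 <= res$ci_high)
  }
  expect_gte(cover, 18)
})

test_that("Cox check reports Schoenfeld diagnostics", {
  cohort <- mk_cc_cohort(500, seed = 17)
  withr::with_seed(18, {
    cohort$entry_day <- 0
    t_raw <- 365 + ceiling(rexp(500, 1 / 900))
    cohort$event_day <- ifelse(cohort$outcome == 1, pmin(t_raw, 3650), NA)
    cohort$censor_day <- ifelse(cohort$outcome == 1, NA, pmin(t_raw, 3649))
  })
  res <- cox_hazard_check(cohort, 3, covariate_set = "main",
                          exposure_only = TRUE)
  expect_true(res$schoenfeld_p > 0 && res$schoenfeld_p <= 1)
  expect_true(all(c("arm", "time") %in% names(res$residuals)))
  expect_equal(nrow(res$residuals), sum(cohort$outcome))
})
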