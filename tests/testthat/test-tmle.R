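test_that("clever covariate arithmetic", {
  expect_equal(clever_covariate(1, 0.5)$H_obs, 2)
  expect_equal(clever_covariate(0, 0.5)$H_obs, -2)
  expect_equal(clever_covariate(1, 0.25)$H_obs, 4)
  h <- clever_covariate(c(1, 0), c(0.2, 0.2))
  expect_equal(h$H1, c(5, 5))
  expect_equal(h$H0, c(-1.25, -1.25))
  expect_error(clever_covariate(1, 1), class = "ehrtmle_estimation_error")
})

test_that("fluctuation solve matches the brute-force likelihood oracle", {
  d <- eight_patient_data()
  eps <- fit_fluctuation(d)
  oracle <- brute_force_epsilon(d$arm, d$y, d$g, d$q1, d$q0)
  expect_lt(abs(eps - oracle), 1e-6)

  # symmetric balanced case solves at exactly zero
  sym <- tibble::tibble(arm = c(1, 1, 0, 0), y = c(1, 0, 1, 0),
                        g = 0.5, q1 = 0.5, q0 = 0.5)
  expect_equal(fit_fluctuation(sym), 0)

  expect_error(fit_fluctuation(dplyr::mutate(d, y = 1)),
               class = "ehrtmle_estimation_error")
})

test_that("epsilon vanishes when initial predictions are correctly specified", {
  dat <- sim_logistic_dgp(20000, seed = 55)
  inputs <- tibble::tibble(arm = dat$arm, y = dat$outcome, g = dat$g_true,
                           q1 = dat$q1_true, q0 = dat$q0_true)
  eps <- fit_fluctuation(inputs)
  h <- clever_covariate(inputs$arm, inputs$g)$H_obs
  qobs <- ifelse(inputs$arm == 1, inputs$q1, inputs$q0)
  se_eps <- 1 / sqrt(sum(h^2 * qobs * (1 - qobs)))
  expect_lt(abs(eps), 3 * se_eps)
})

test_that("targeting update is the offset-logistic shift", {
  d <- eight_patient_data()
  upd0 <- update_predictions(d, 0)
  expect_equal(upd0$q1, d$q1)
  expect_equal(upd0$q0, d$q0)
  one <- tibble::tibble(arm = 1, y = 1, g = 0.5, q1 = 0.5, q0 = 0.5)
  expect_equal(update_predictions(one, 0.1)$q1, plogis(0.2))
  # two-dimensional fluctuation updates each arm with its own coefficient
  upd2 <- update_predictions(one, c(0.1, 0.3))
  expect_equal(upd2$q1, plogis(0.2))
  expect_equal(upd2$q0, plogis(qlogis(0.5) + 0.3 * (-1 / 0.5)))
  # monotonicity: larger epsilon raises q1* and lowers q0* everywhere
  withr::with_seed(3, {
    dd <- tibble::tibble(arm = rbinom(50, 1, 0.5), y = rbinom(50, 1, 0.4),
                         g = runif(50, 0.1, 0.9), q1 = runif(50, 0.05, 0.95),
                         q0 = runif(50, 0.05, 0.95))
    for (e in c(-0.5, 0, 0.5)) {
      a <- update_predictions(dd, e)
      b <- update_predictions(dd, e + 0.2)
      expect_true(all(b$q1 > a$q1))
      expect_true(all(b$q0 < a$q0))
    }
  })
})

test_that("marginal risks average both arms over everyone", {
  expect_equal(unname(marginal_risks(rep(0.3, 10), rep(0.1, 10))), c(0.3, 0.1))
  withr::with_seed(4, {
    q1 <- runif(30); q0 <- runif(30)
    p <- sample(30)
    expect_equal(marginal_risks(q1, q0), marginal_risks(q1[p], q0[p]))
  })
  expect_error(marginal_risks(numeric(0), numeric(0)),
               class = "ehrtmle_estimation_error")
})

test_that("saturated one-covariate standardization matches the 2-cell closed form", {
  withr::with_seed(6, {
    x <- rbinom(120, 1, 0.4)
    arm <- rbinom(120, 1, 0.3 + 0.4 * x)
    y <- rbinom(120, 1, 0.2 + 0.3 * arm + 0.2 * x)
  })
  cell <- function(a, xx) mean(y[arm == a & x == xx])
  q1_hat <- ifelse(x == 1, cell(1, 1), cell(1, 0))
  q0_hat <- ifelse(x == 1, cell(0, 1), cell(0, 0))
  psi <- marginal_risks(q1_hat, q0_hat)
  expect_equal(unname(psi["psi1"]),
               mean(x) * cell(1, 1) + (1 - mean(x)) * cell(1, 0),
               tolerance = 1e-12)
  expect_equal(unname(psi["psi0"]),
               mean(x) * cell(0, 1) + (1 - mean(x)) * cell(0, 0),
               tolerance = 1e-12)
})

test_that("targeting solves the score equation and reports diagnostics", {
  dat <- sim_logistic_dgp(3000, seed = 77)
  nu <- dgp_nuisances(dat)
  est <- cv_tmle_rr(nu, "cat5_vs_ref")
  expect_lt(abs(est$score_residual), 1e-8)
  expect_true(est$ci_low <= est$rr && est$rr <= est$ci_high)
  expect_equal(est$n1 + est$n0, 3000)
  # per-fold variant also solves its score equations
  pf <- cv_tmle_rr(nu, "cat5_vs_ref", variant = "per_fold")
  expect_lt(abs(pf$score_residual), 1e-6)
  # two-dimensional fluctuation gives a similar estimate
  two <- cv_tmle_rr(nu, "cat5_vs_ref", two_dim = TRUE)
  expect_equal(two$rr, est$rr, tolerance = 0.05)
})

test_that("forcing epsilon to zero reduces exactly to the g-computation plug-in", {
  dat <- sim_logistic_dgp(800, seed = 78)
  nu <- dgp_nuisances(dat)
  plug <- cv_tmle_rr(nu, "x", fluctuate = FALSE)
  expect_identical(plug$epsilon, 0)
  expect_equal(plug$rr, mean(nu$q1) / mean(nu$q0), tolerance = 1e-12)
  expect_equal(plug$method, "plugin")
})

test_that("constant propensity with saturated outcome reproduces the crude RR", {
  withr::with_seed(91, {
    arm <- rbinom(400, 1, 0.35)
    y <- rbinom(400, 1, 0.2 + 0.2 * arm)
  })
  nu <- tibble::tibble(pid = as.character(seq_along(arm)),
                       fold = (seq_along(arm) - 1L) %% 5L, arm = arm, y = y,
                       g = mean(arm), q1 = mean(y[arm == 1]),
                       q0 = mean(y[arm == 0]))
  est <- cv_tmle_rr(nu, "x")
  crude <- mean(y[arm == 1]) / mean(y[arm == 0])
  expect_equal(est$rr, crude, tolerance = 1e-10)
  expect_lt(abs(est$epsilon), 1e-8)
})

test_that("pooled result equals single-split targeting when folds coincide", {
  dat <- sim_logistic_dgp(500, seed = 79)
  nu <- dgp_nuisances(dat)
  # replicate the same held-out set across all folds: per-fold targeting then
  # agrees with one pooled fluctuation on the original data
  rep5 <- dplyr::bind_rows(lapply(0:4, function(f)
    dplyr::mutate(nu, fold = f, pid = paste0(pid, "_", f))))
  single <- cv_tmle_rr(nu, "x")
  perfold <- cv_tmle_rr(rep5, "x", variant = "per_fold")
  expect_equal(perfold$rr, single$rr, tolerance = 1e-10)
})

test_that("nuisance contract violations are rejected", {
  dat <- sim_logistic_dgp(200, seed = 80)
  nu <- dgp_nuisances(dat)
  expect_error(cv_tmle_rr(dplyr::bind_rows(nu, nu[1, ]), "x"),
               class = "ehrtmle_contract_error")
  expect_error(cv_tmle_rr(nu[nu$fold != 2, ], "x"),
               class = "ehrtmle_contract_error")
})

test_that("nuisance JSON-lines round-trip", {
  dat <- sim_logistic_dgp(60, seed = 81)
  nu <- dgp_nuisances(dat)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_nuisances(nu, path)
  back <- read_nuisances(path)
  cols <- c("pid", "fold", "arm", "y", "g", "q1", "q0")
  orig <- tibble::as_tibble(nu)[cols]
  attr(orig, "fold_train_pids") <- NULL
  expect_equal(tibble::as_tibble(back)[cols], orig)
})

test_that("CI width shrinks like n^{-1/2}", {
  ns <- c(500, 2000, 8000)
  widths <- vapply(seq_along(ns), function(i) {
    w <- vapply(1:8, function(r) {
      dat <- sim_logistic_dgp(ns[i], seed = 1000 * i + r)
      inputs <- tibble::tibble(pid = dat$pid, fold = dat$fold, arm = dat$arm,
                               y = dat$outcome, g = dat$g_true,
                               q1 = dat$q1_true, q0 = dat$q0_true)
      est <- cv_tmle_rr(inputs, "x")
      log(est$ci_high) - log(est$ci_low)
    }, numeric(1))
    mean(w)
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})
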