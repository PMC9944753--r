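test_that("configuration invariants are enforced", {
  expect_error(sim_config(0), class = "ehrtmle_config_error")
  expect_error(sim_config(10, category_effects = c(0.1, 0, 0, 0, 0, 0)),
               class = "ehrtmle_config_error")
  expect_error(sim_config(10, category_effects = rep(0, 5)),
               class = "ehrtmle_config_error")
  expect_error(sim_config(10, sbp_noise_sd = 0), class = "ehrtmle_config_error")
  expect_error(oracle_true_rr(sim_config(10), 6), class = "ehrtmle_config_error")
})

test_that("population generation is deterministic given the seed", {
  cfg <- sim_config(200, seed = 7)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$patients, p2$patients)
  expect_identical(p1$events, p2$events)
  expect_identical(p1$measurements, p2$measurements)
  expect_equal(nrow(p1$patients), 200)
})

test_that("generated records respect structural invariants", {
  pop <- shared_pop()
  expect_true(all(pop$patients$pid == sprintf("p%06d", seq_len(500))))
  risks <- as.matrix(pop$patients[paste0("risk_cat", 0:5)])
  expect_true(all(risks > 0 & risks < 1))
  # risks rise with the category effect for every patient (monotone effects)
  expect_true(all(diff(t(risks)) >= 0))
  # event days non-decreasing within each patient after the writer's sort
  sorted_by_pid <- tapply(pop$events$day, pop$events$pid,
                          function(d) !is.unsorted(d))
  expect_true(all(sorted_by_pid))
  expect_true(all(pop$measurements$sbp > 40 & pop$measurements$sbp < 330))
})

test_that("null generator shows no outcome gradient across realized categories", {
  cfg <- sim_config(20000, seed = 31, conf_strength = 0,
                    category_effects = rep(0, 6),
                    covariate_effects = c(age = 0))
  pop <- generate_population(cfg)
  pts <- pop$patients
  p_all <- mean(pts$latent_y)
  for (cat in 0:5) {
    sel <- pts$latent_cat == cat
    if (sum(sel) < 50) next
    p_cat <- mean(pts$latent_y[sel])
    se <- sqrt(p_cat * (1 - p_cat) / sum(sel) + p_all * (1 - p_all) / nrow(pts))
    expect_lt(abs(p_cat - p_all), 3 * se + 1e-12)
  }
})

test_that("frailty induces crude confounding when true effects are null", {
  cfg <- sim_config(20000, seed = 32, conf_strength = 0.8,
                    category_effects = rep(0, 6))
  pop <- generate_population(cfg)
  pts <- pop$patients
  top <- pts$latent_cat == 5; ref <- pts$latent_cat == 0
  p1 <- mean(pts$latent_y[top]); p0 <- mean(pts$latent_y[ref])
  crude <- p1 / p0
  se_log <- sqrt((1 - p1) / (p1 * sum(top)) + (1 - p0) / (p0 * sum(ref)))
  expect_gt(log(crude), 2 * se_log)  # crude RR > 1 while true RR = 1
})

test_that("exchangeability: exposure realization leaves potential risks unchanged", {
  base <- sim_config(300, seed = 5, sbp_conf_slope = 8)
  flip <- sim_config(300, seed = 5, sbp_conf_slope = -14)
  p1 <- generate_population(base)
  p2 <- generate_population(flip)
  expect_identical(p1$patients[paste0("risk_cat", 0:5)],
                   p2$patients[paste0("risk_cat", 0:5)])
  expect_false(identical(p1$patients$latent_cat, p2$patients$latent_cat))
})

test_that("oracle reference ratio is exactly 1 and null effects give RR 1", {
  cfg <- sim_config(100, seed = 2)
  expect_identical(oracle_true_rr(cfg, 0, n_mc = 1000)$rr, 1.0)
  null_cfg <- sim_config(100, seed = 2, category_effects = rep(0, 6))
  for (cat in 1:5) {
    o <- oracle_true_rr(null_cfg, cat, n_mc = 50000, seed = 9)
    expect_lt(abs(o$rr - 1), 3 * o$se + 1e-12)
  }
})

test_that("oracle agrees with exhaustive quadrature over the discrete covariate grid", {
  cfg <- sim_config(100, seed = 3,
                    conf_strength = 0.8,
                    category_effects = c(0, 0, 0, 0, 0, log(1.5)),
                    covariate_effects = c(sex_M = 0.3, af = 0.5, ckd = 0.4))
  # independent oracle: integrate U by quadrature, sum the discrete cells
  # (sex ~ Bern(0.45 F); af ~ Bern(expit(-3 + 0.6 U)); ckd ~ Bern(expit(-3 + 0.7 U)))
  cell_mean <- function(beta_a) {
    integrand <- function(u) {
      p_af <- plogis(-3 + 0.6 * u); p_ckd <- plogis(-3 + 0.7 * u)
      acc <- 0
      for (sexM in 0:1) for (af in 0:1) for (ckd in 0:1) {
        w <- ifelse(sexM == 1, 0.55, 0.45) *
          ifelse(af == 1, p_af, 1 - p_af) * ifelse(ckd == 1, p_ckd, 1 - p_ckd)
        acc <- acc + w * plogis(cfg$baseline_logodds + beta_a +
                                  0.3 * sexM + 0.5 * af + 0.4 * ckd + 0.8 * u)
      }
      acc * dnorm(u)
    }
    integrate(Vectorize(integrand), -8, 8, rel.tol = 1e-10)$value
  }
  expected_rr <- cell_mean(log(1.5)) / cell_mean(0)
  o <- oracle_true_rr(cfg, 5, n_mc = 2e5, seed = 77)
  expect_lt(abs(o$rr - expected_rr), 3 * o$se)
})

test_that("marginal risks converge to the analytic expectation", {
  cfg <- sim_config(20000, seed = 41,
                    covariate_effects = c(sex_M = 0.25, af = 0.5, ckd = 0.4))
  o <- oracle_true_rr(cfg, 0, n_mc = 20000, seed = 41)
  integrand <- function(u) {
    p_af <- plogis(-3 + 0.6 * u); p_ckd <- plogis(-3 + 0.7 * u)
    acc <- 0
    for (sexM in 0:1) for (af in 0:1) for (ckd in 0:1) {
      w <- ifelse(sexM == 1, 0.55, 0.45) *
        ifelse(af == 1, p_af, 1 - p_af) * ifelse(ckd == 1, p_ckd, 1 - p_ckd)
      acc <- acc + w * plogis(cfg$baseline_logodds + 0.25 * sexM + 0.5 * af +
                                0.4 * ckd + cfg$conf_strength * u)
    }
    acc * dnorm(u)
  }
  psi_exact <- integrate(Vectorize(integrand), -8, 8, rel.tol = 1e-10)$value
  se <- sqrt(psi_exact * (1 - psi_exact) / 20000)
  expect_lt(abs(o$psi - psi_exact), 4 * se)
})

test_that("population writers round-trip losslessly", {
  pop <- shared_pop()
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  back <- read_population(dir)
  expect_equal(back$patients, pop$patients)
  expect_equal(back$events, pop$events)
  expect_equal(back$measurements, pop$measurements)
  expect_equal(unclass(back$config), unclass(pop$config))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$true_rr[1], 1)
  expect_equal(truth$true_marginal_risks,
               unname(colMeans(as.matrix(pop$patients[paste0("risk_cat", 0:5)]))))
})
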