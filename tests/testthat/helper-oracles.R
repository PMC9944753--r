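# Independent oracles used to freeze expected values.

# Brute-force fluctuation oracle: maximize the binomial log-likelihood of the
# offset-logistic submodel by golden-section search (stats::optimize), fully
# independent of the Newton solver under test.
brute_force_epsilon <- function(A, y, g, q1, q0, lo = -10, hi = 10) {
  qobs <- pmin(pmax(ifelse(A == 1, q1, q0), 1e-9), 1 - 1e-9)
  H <- A / g - (1 - A) / (1 - g)
  off <- qlogis(qobs)
  negll <- function(eps) {
    p <- plogis(off + eps * H)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  optimize(negll, c(lo, hi), tol = 1e-10)$minimum
}

# Fixed 8-patient dataset for the targeting-step checks.
eight_patient_data <- function() {
  tibble::tibble(
    arm = c(1, 1, 1, 1, 0, 0, 0, 0),
    y   = c(1, 0, 1, 1, 0, 0, 1, 0),
    g   = c(0.7, 0.6, 0.5, 0.8, 0.3, 0.4, 0.2, 0.5),
    q1  = c(0.6, 0.5, 0.4, 0.7, 0.5, 0.45, 0.3, 0.55),
    q0  = c(0.3, 0.25, 0.2, 0.4, 0.35, 0.3, 0.15, 0.45))
}

# Simple logistic data-generating process with known standardized risks:
# x1 ~ N(0,1), x2 ~ Bern(0.5); A ~ Bern(expit(a0 + a1 x1 + a2 x2));
# Y ~ Bern(expit(b0 + bA A + b1 x1 + b2 x2)).
sim_logistic_dgp <- function(n, seed, a = c(-0.2, 0.5, 0.4),
                             b = c(-1, 0.7, 0.6, 0.5), n_folds = 5L) {
  withr::with_seed(seed, {
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
    g <- plogis(a[1] + a[2] * x1 + a[3] * x2)
    arm <- rbinom(n, 1, g)
    q <- function(aa) plogis(b[1] + b[2] * aa + b[3] * x1 + b[4] * x2)
    y <- rbinom(n, 1, ifelse(arm == 1, q(1), q(0)))
    tibble::tibble(pid = sprintf("s%06d", seq_len(n)), x1 = x1, x2 = x2,
                   arm = arm, outcome = y, g_true = g,
                   q1_true = q(1), q0_true = q(0),
                   fold = (seq_len(n) - 1L) %% n_folds,
                   exposure_cat = ifelse(arm == 1, 5L, 0L))
  })
}

# True marginal RR of the logistic DGP by large Monte-Carlo standardization.
true_rr_logistic <- function(b = c(-1, 0.7, 0.6, 0.5), n_mc = 2e6, seed = 424242) {
  withr::with_seed(seed, {
    x1 <- rnorm(n_mc); x2 <- rbinom(n_mc, 1, 0.5)
    mean(plogis(b[1] + b[2] + b[3] * x1 + b[4] * x2)) /
      mean(plogis(b[1] + b[3] * x1 + b[4] * x2))
  })
}

# Cross-fitted correctly-specified glm nuisances for the logistic DGP.
dgp_nuisances <- function(dat, outcome_features = c("x1", "x2"),
                          delta = 0.01) {
  crossfit_glm_nuisances(dat, 5L, features = c("x1", "x2"),
                         outcome_features = outcome_features, delta = delta)
}
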