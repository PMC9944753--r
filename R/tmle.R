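# Cross-validated targeted maximum likelihood estimation of the marginal
# risk ratio for a binary exposure contrast: logistic fluctuation of the
# initial outcome predictions along the clever covariate, direct
# standardization of the targeted predictions, and influence-curve CIs.

#' Clever covariate for the risk-ratio targeting step
#'
#' `H1 = 1/g`, `H0 = -1/(1-g)`, and the observed-arm value
#' `H_obs = A/g - (1-A)/(1-g)`.
#'
#' @param A Binary arm indicator (1 = comparison category).
#' @param g Propensity of the comparison arm, in (0, 1).
#' @return List with `H1`, `H0`, `H_obs`.
#' @export
clever_covariate <- function(A, g) {
  if (any(g <= 0 | g >= 1)) {
    abort("Propensities must lie strictly inside (0, 1); clip upstream.",
          class = "ehrtmle_estimation_error")
  }
  list(H1 = 1 / g, H0 = -1 / (1 - g), H_obs = A / g - (1 - A) / (1 - g))
}

qbound <- function(q) clip(q, 1e-9, 1 - 1e-9)

#' Fit the fluctuation coefficient
#'
#' Maximizes the binomial log-likelihood of `y` under the submodel
#' `expit(logit(q_obs) + eps * H_obs)` (offset logit, single covariate, no
#' intercept) by Newton iterations until the mean score falls below `tol`.
#'
#' @param inputs Tibble/data frame with columns `arm` (or `A`), `y`, `g`,
#'   `q1`, `q0`.
#' @param tol Convergence tolerance on `|mean(H_obs * (y - q))|`.
#' @param max_iter Newton iteration cap; exceeding it is an error.
#' @param two_dim If `TRUE`, fit separate coefficients `(eps1, eps0)` for the
#'   two arm-specific submodels (the fluctuations separate over arms, so each
#'   is a one-dimensional solve on its own arm's data).
#' @return Numeric `epsilon` (length 1, or 2 when `two_dim`).
#' @export
fit_fluctuation <- function(inputs, tol = 1e-12, max_iter = 100L,
                            two_dim = FALSE) {
  inp <- normalize_tmle_inputs(inputs)
  if (length(unique(inp$A)) < 2 || length(unique(inp$y)) < 2) {
    abort("Fluctuation needs both arms and both outcome values present.",
          class = "ehrtmle_estimation_error")
  }
  if (two_dim) {
    e1 <- solve_fluct(inp$y[inp$A == 1], qbound(inp$q1[inp$A == 1]),
                      1 / inp$g[inp$A == 1], tol, max_iter)
    e0 <- solve_fluct(inp$y[inp$A == 0], qbound(inp$q0[inp$A == 0]),
                      -1 / (1 - inp$g[inp$A == 0]), tol, max_iter)
    return(c(e1, e0))
  }
  qobs <- qbound(ifelse(inp$A == 1, inp$q1, inp$q0))
  H <- clever_covariate(inp$A, inp$g)$H_obs
  solve_fluct(inp$y, qobs, H, tol, max_iter)
}

solve_fluct <- function(y, q0, H, tol, max_iter) {
  off <- logit(q0)
  eps <- 0
  for (it in seq_len(max_iter)) {
    q <- expit(off + eps * H)
    score <- mean(H * (y - q))
    if (abs(score) < tol) return(eps)
    info <- mean(H^2 * q * (1 - q))
    if (info < 1e-14) {
      abort("Singular information in the fluctuation solve.",
            class = "ehrtmle_estimation_error")
    }
    step <- score / info
    eps <- eps + sign(step) * min(abs(step), 10)  # damped for extreme H
  }
  abort(sprintf("Fluctuation did not converge in %d iterations (|score|=%.3g).",
                max_iter, abs(score)),
        class = "ehrtmle_estimation_error")
}

normalize_tmle_inputs <- function(inputs) {
  A <- inputs$arm %||% inputs$A
  if (is.null(A)) abort("Inputs need an `arm` (or `A`) column.",
                        class = "ehrtmle_contract_error")
  list(A = as.numeric(A), y = as.numeric(inputs$y), g = as.numeric(inputs$g),
       q1 = as.numeric(inputs$q1), q0 = as.numeric(inputs$q0))
}

#' Apply the targeting update to both arm-specific predictions
#'
#' `q_a* = expit(logit(q_a) + eps * H_a)` with `H1 = 1/g`, `H0 = -1/(1-g)`;
#' with a length-2 `epsilon`, each arm uses its own coefficient.
#'
#' @inheritParams fit_fluctuation
#' @param epsilon Fluctuation coefficient(s) from [fit_fluctuation()].
#' @return Tibble with updated `q1`, `q0`.
#' @export
update_predictions <- function(inputs, epsilon) {
  inp <- normalize_tmle_inputs(inputs)
  H <- clever_covariate(inp$A, inp$g)
  e1 <- epsilon[1]
  e0 <- if (length(epsilon) > 1) epsilon[2] else epsilon[1]
  tibble::tibble(q1 = expit(logit(qbound(inp$q1)) + e1 * H$H1),
                 q0 = expit(logit(qbound(inp$q0)) + e0 * H$H0))
}

#' Marginal risks by direct standardization
#'
#' Averages the (targeted) arm-specific predictions over *all* patients in
#' the contrast, regardless of observed arm.
#'
#' @param q1,q0 Per-patient predicted risks under the comparison and
#'   reference arm.
#' @return Named numeric vector `c(psi1, psi0)`.
#' @export
marginal_risks <- function(q1, q0) {
  if (length(q1) == 0) abort("Empty cohort.", class = "ehrtmle_estimation_error")
  c(psi1 = mean(q1), psi0 = mean(q0))
}

new_rr_estimate <- function(rr, ci_low, ci_high, log_se, method, contrast,
                            epsilon = NA_real_, score_residual = NA_real_,
                            n1 = NA_integer_, n0 = NA_integer_,
                            events1 = NA_integer_, events0 = NA_integer_,
                            extra = list()) {
  structure(c(list(rr = rr, ci_low = ci_low, ci_high = ci_high, log_se = log_se,
                   epsilon = epsilon, score_residual = score_residual,
                   method = method, contrast = contrast, n1 = n1, n0 = n0,
                   events1 = events1, events0 = events0), extra),
            class = "rr_estimate")
}

#' @exportS3Method base::print
print.rr_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "no CI" else sprintf("95%% CI %.3f-%.3f",
                                                  x$ci_low, x$ci_high)
  cat(sprintf("<rr_estimate> %s %s: RR %.3f (%s)\n", x$method, x$contrast,
              x$rr, ci))
  invisible(x)
}

#' Risk ratio with influence-curve confidence interval
#'
#' Given targeted predictions, computes `rr = psi1/psi0`, the efficient
#' influence curve of `log(rr)` (`IC_a = H_a 1{A=a}(y - q_a*) + q_a* - psi_a`
#' combined as `IC1/psi1 - IC0/psi0`), its variance-based 95% CI, and the
#' residual of the targeting score equation.
#'
#' @inheritParams fit_fluctuation
#' @param q1_star,q0_star Targeted per-patient predictions.
#' @param epsilon Fluctuation coefficient(s) used (diagnostics).
#' @param method,contrast Labels carried in the estimate.
#' @return An `rr_estimate`.
#' @export
rr_with_ci <- function(inputs, q1_star, q0_star, epsilon = NA_real_,
                       method = "cv_tmle", contrast = NA_character_) {
  inp <- normalize_tmle_inputs(inputs)
  psi <- marginal_risks(q1_star, q0_star)
  if (psi["psi0"] <= 0) {
    abort("Reference marginal risk is zero; risk ratio undefined.",
          class = "ehrtmle_estimation_error")
  }
  n <- length(inp$y)
  ic1 <- (inp$A / inp$g) * (inp$y - q1_star) + q1_star - psi["psi1"]
  ic0 <- ((1 - inp$A) / (1 - inp$g)) * (inp$y - q0_star) + q0_star - psi["psi0"]
  ic <- ic1 / psi["psi1"] - ic0 / psi["psi0"]
  log_se <- sd(ic) / sqrt(n)
  rr <- unname(psi["psi1"] / psi["psi0"])
  H <- clever_covariate(inp$A, inp$g)
  qobs_star <- ifelse(inp$A == 1, q1_star, q0_star)
  new_rr_estimate(
    rr = rr,
    ci_low = exp(log(rr) - 1.96 * log_se),
    ci_high = exp(log(rr) + 1.96 * log_se),
    log_se = log_se, epsilon = epsilon,
    score_residual = mean(H$H_obs * (inp$y - qobs_star)),
    method = method, contrast = contrast,
    n1 = sum(inp$A == 1), n0 = sum(inp$A == 0),
    events1 = sum(inp$y[inp$A == 1]), events0 = sum(inp$y[inp$A == 0]),
    extra = list(psi1 = unname(psi["psi1"]), psi0 = unname(psi["psi0"])))
}

#' Cross-validated TMLE of the risk ratio
#'
#' Pools the held-out nuisance estimates across folds, fits the fluctuation,
#' updates both arm-specific predictions, and returns the standardized risk
#' ratio with its influence-curve CI. With `fluctuate = FALSE` the estimator
#' reduces exactly to the g-computation plug-in on the initial predictions.
#'
#' @param nuisances A `nuisance_estimates` tibble (complete held-out
#'   coverage: every patient exactly once, every fold represented).
#' @param contrast Label, e.g. `"cat5_vs_ref"`.
#' @param fluctuate Apply the targeting step (default) or report the plug-in.
#' @param variant `"pooled"` fits one fluctuation on all held-out
#'   predictions; `"per_fold"` fits a fluctuation within each fold and pools
#'   the targeted predictions.
#' @param two_dim Use separate fluctuation coefficients per arm.
#' @return An `rr_estimate`.
#' @export
cv_tmle_rr <- function(nuisances, contrast = NA_character_, fluctuate = TRUE,
                       variant = c("pooled", "per_fold"), two_dim = FALSE) {
  variant <- match.arg(variant)
  if (anyDuplicated(nuisances$pid)) {
    abort("Each patient must appear exactly once in the nuisance estimates.",
          class = "ehrtmle_contract_error")
  }
  folds <- sort(unique(as.integer(nuisances$fold)))
  if (!all(seq(min(folds), max(folds)) %in% folds)) {
    abort("Missing fold coverage in the nuisance estimates.",
          class = "ehrtmle_contract_error")
  }
  if (!fluctuate) {
    eps <- if (two_dim) c(0, 0) else 0
    upd <- update_predictions(nuisances, eps)
    return(rr_with_ci(nuisances, upd$q1, upd$q0, epsilon = eps,
                      method = "plugin", contrast = contrast))
  }
  if (variant == "pooled") {
    eps <- fit_fluctuation(nuisances, two_dim = two_dim)
    upd <- update_predictions(nuisances, eps)
    return(rr_with_ci(nuisances, upd$q1, upd$q0, epsilon = eps,
                      method = "cv_tmle", contrast = contrast))
  }
  q1s <- q0s <- numeric(nrow(nuisances))
  eps_all <- c()
  for (f in folds) {
    sel <- nuisances$fold == f
    eps <- fit_fluctuation(nuisances[sel, ], two_dim = two_dim)
    upd <- update_predictions(nuisances[sel, ], eps)
    q1s[sel] <- upd$q1; q0s[sel] <- upd$q0
    eps_all <- c(eps_all, eps)
  }
  rr_with_ci(nuisances, q1s, q0s, epsilon = mean(eps_all),
             method = "cv_tmle_per_fold", contrast = contrast)
}
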