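# Multiple imputation by chained equations for the baseline covariates.
# Continuous variables use Bayesian-draw linear regression; smoking status
# uses a multinomial-logistic draw. The outcome and exposure category are
# always included as predictors, per standard practice.

MICE_CONTINUOUS <- c("bmi", "hdl", "total_chol", "triglycerides")
MICE_CATEGORICAL <- "smoking"

#' Multiple imputation by chained equations
#'
#' Imputes the declared-imputable baseline covariates (`bmi`, `hdl`,
#' `total_chol`, `triglycerides`, `smoking`, plus any of `extra_continuous`,
#' e.g. `hba1c_mean_12m` for the extended covariate set) by cycling
#' per-variable regressions `iterations` times within each of `m`
#' imputations. Continuous variables are imputed by Bayesian linear
#' regression draws (posterior draws of the coefficients and residual
#' variance); smoking by draws from multinomial-logistic predicted
#' probabilities. The outcome and the exposure category enter every
#' imputation model as predictors. Deterministic given `seed`.
#'
#' @param table Cohort tibble (needs the imputable columns plus
#'   `exposure_cat`, `outcome`, `age_at_entry`, `sex`).
#' @param m Number of completed tables.
#' @param iterations Chained-equation cycles per imputation.
#' @param seed Integer seed.
#' @param extra_continuous Additional continuous columns to impute.
#' @return A list of class `imputation_set`: `completed` (list of `m`
#'   tibbles), `m`, `seed`.
#' @export
mice_impute <- function(table, m = 25L, iterations = 10L, seed = 1L,
                        extra_continuous = character(0)) {
  stopifnot(m >= 1)
  cont <- c(intersect(MICE_CONTINUOUS, names(table)), extra_continuous)
  cat_vars <- intersect(MICE_CATEGORICAL, names(table))
  imp_vars <- c(cont, cat_vars)
  fully_missing <- imp_vars[vapply(imp_vars, function(v) all(is.na(table[[v]])),
                                   logical(1))]
  if (length(fully_missing)) {
    abort(sprintf("Column(s) fully missing: %s.",
                  paste(fully_missing, collapse = ", ")),
          class = "ehrtmle_config_error")
  }
  base_preds <- intersect(c("age_at_entry", "sex"), names(table))
  has_na <- imp_vars[vapply(imp_vars, function(v) anyNA(table[[v]]), logical(1))]
  if (length(has_na) == 0) {
    return(structure(list(completed = replicate(m, table, simplify = FALSE),
                          m = as.integer(m), seed = as.integer(seed)),
                     class = "imputation_set"))
  }
  completed <- with_seed(seed, {
    lapply(seq_len(m), function(im) {
      tab <- table
      # initialize missing entries by sampling observed values
      for (v in has_na) {
        miss <- is.na(tab[[v]])
        tab[[v]][miss] <- sample(tab[[v]][!miss], sum(miss), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (v in has_na) {
          miss <- is.na(table[[v]])
          preds <- c(setdiff(imp_vars, v), base_preds, "exposure_cat", "outcome")
          rhs <- paste(preds, collapse = " + ")
          dat <- tab
          dat$exposure_cat <- factor(dat$exposure_cat)
          if (v %in% cont) {
            X <- model.matrix(as.formula(paste("~", rhs)), dat)
            yv <- tab[[v]]
            fit <- stats::lm.fit(X[!miss, , drop = FALSE], yv[!miss])
            keep <- !is.na(fit$coefficients)
            Xo <- X[!miss, keep, drop = FALSE]
            beta <- fit$coefficients[keep]
            res <- fit$residuals
            df <- max(length(res) - ncol(Xo), 2)
            sigma2 <- sum(res^2) / stats::rchisq(1, df)
            XtX_inv <- chol2inv(chol(crossprod(Xo) +
                                       diag(1e-8, ncol(Xo))))
            beta_draw <- beta + drop(chol(sigma2 * XtX_inv +
                                            diag(1e-12, ncol(Xo))) %*% rnorm(ncol(Xo)))
            mu <- X[miss, keep, drop = FALSE] %*% beta_draw
            tab[[v]][miss] <- drop(mu) + rnorm(sum(miss), 0, sqrt(sigma2))
          } else {
            dat[[v]] <- factor(tab[[v]])
            fit <- suppressWarnings(
              nnet::multinom(as.formula(paste(v, "~", rhs)),
                             data = dat[!miss, , drop = FALSE], trace = FALSE))
            pr <- predict(fit, newdata = dat[miss, , drop = FALSE],
                          type = "probs")
            if (is.null(dim(pr))) pr <- rbind(pr)
            lev <- fit$lev
            if (ncol(pr) == 1) pr <- cbind(1 - pr, pr)
            draws <- apply(pr, 1, function(p) sample(lev, 1, prob = p))
            tab[[v]][miss] <- draws
          }
        }
      }
      tab
    })
  })
  structure(list(completed = completed, m = as.integer(m),
                 seed = as.integer(seed)),
            class = "imputation_set")
}

#' @exportS3Method base::print
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed tables (%d rows)\n",
              x$m, nrow(x$completed[[1]])))
  invisible(x)
}
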