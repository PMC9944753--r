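# Cross-fitted nuisance estimation: for each fold, nuisance models are
# trained on the other folds and evaluated on the held-out fold, so no
# patient's propensity/outcome prediction comes from a model that saw them.

pairwise_subset <- function(cohort, category) {
  if (!(category %in% 1:5)) {
    abort("`category` must be in 1..5 (pairwise contrast vs the reference).",
          class = "ehrtmle_config_error")
  }
  sub <- cohort[cohort$exposure_cat %in% c(0L, category), , drop = FALSE]
  sub$arm <- as.integer(sub$exposure_cat == category)
  sub
}

check_fold_classes <- function(sub, n_folds) {
  for (f in seq_len(n_folds) - 1L) {
    tr <- sub[sub$fold != f, ]
    if (length(unique(tr$arm)) < 2 || length(unique(tr$outcome)) < 2) {
      abort(sprintf(paste0("Degenerate fold %d: training data has a single ",
                           "exposure or outcome class."), f),
            class = "ehrtmle_degenerate_fold")
    }
  }
}

#' Assemble per-patient history inputs for the sequence model
#'
#' @param cohort Cohort tibble (needs `pid`, `entry_day`, `sex`, `smoking`).
#' @param population The source `ehr_population`.
#' @return Named list (by pid) of per-patient lists consumable by
#'   [tokenize_history()].
#' @export
history_inputs <- function(cohort, population) {
  ev <- population$events
  ev_split <- split(seq_len(nrow(ev)), ev$pid)
  pts <- population$patients
  birth <- setNames(pts$birth_day, pts$pid)
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$pid
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$pid[i]
    out[[i]] <- list(pid = pid, sex = cohort$sex[i], smoking = cohort$smoking[i],
                     birth_day = unname(birth[pid]),
                     entry_day = cohort$entry_day[i],
                     events = ev[ev_split[[pid]] %||% integer(), ])
  }
  out
}

#' Cross-fitted nuisance estimates from the EHR transformer
#'
#' Restricts the cohort to the reference category and one comparison
#' category, then for each fold trains a fresh transformer on the remaining
#' folds (joint masked-sequence + propensity + outcome objective) and
#' predicts the held-out fold's propensity `g` and arm-specific outcome risks
#' `q1`, `q0`. The vocabulary is rebuilt from each fold's training histories,
#' so codes unseen in training map to `[UNK]` at prediction time.
#' Propensities are clipped to `[delta, 1 - delta]`.
#'
#' @param cohort Cohort tibble from [build_cohort()] (with folds assigned).
#' @param population The source `ehr_population`.
#' @param category Comparison exposure category in 1..5.
#' @param config A [model_config()].
#' @return A `nuisance_estimates` tibble with columns `pid`, `fold`, `arm`,
#'   `y`, `g`, `q1`, `q0`; attribute `fold_train_pids` records which patients
#'   each fold's model was trained on.
#' @export
train_crossfit <- function(cohort, population, category, config = model_config()) {
  sub <- pairwise_subset(cohort, category)
  n_folds <- max(sub$fold) + 1L
  check_fold_classes(sub, n_folds)
  hist_in <- history_inputs(sub, population)
  res <- vector("list", n_folds)
  train_pids <- vector("list", n_folds)
  for (f in seq_len(n_folds) - 1L) {
    tr <- which(sub$fold != f)
    te <- which(sub$fold == f)
    train_pids[[f + 1L]] <- sub$pid[tr]
    corpus <- unlist(lapply(hist_in[tr], function(p) p$events$code))
    vocab <- build_vocabulary(if (length(corpus)) corpus else "dx_none")
    tok <- function(idx) lapply(hist_in[idx], function(p)
      tokenize_history(p, p$entry_day, vocab, config$max_len))
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, 31L + f)
    fit <- train_model(tok(tr), sub$arm[tr], sub$outcome[tr], vocab, cfg_f)
    pred <- model_predict(fit$params, tok(te), vocab, config)
    res[[f + 1L]] <- tibble::tibble(pid = sub$pid[te], fold = f,
                                    arm = sub$arm[te], y = sub$outcome[te],
                                    g = pred$g, q1 = pred$q1, q0 = pred$q0)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "fold_train_pids") <- train_pids
  class(out) <- c("nuisance_estimates", class(out))
  out
}

#' Cross-fitted logistic-regression nuisance estimates
#'
#' The same cross-fitting contract as [train_crossfit()] with plain logistic
#' regressions as the nuisance learners: a propensity model `arm ~ features`
#' and an outcome model `outcome ~ arm + features`, both fit on the training
#' folds and evaluated on the held-out fold (with the arm forced to 1 and 0
#' for `q1`/`q0`). Useful as a fast nuisance stand-in and for
#' double-robustness experiments via a deliberately misspecified outcome
#' model.
#'
#' @param cohort Cohort tibble (pairwise restriction applied internally).
#' @param category Comparison exposure category in 1..5.
#' @param features Character vector of cohort column names used as predictors.
#' @param outcome_features Predictors of the outcome model; defaults to
#'   `features`. Use `character(0)` for an intercept-only (misspecified)
#'   outcome model.
#' @param delta Propensity clipping bound.
#' @return A `nuisance_estimates` tibble (see [train_crossfit()]).
#' @export
crossfit_glm_nuisances <- function(cohort, category, features,
                                   outcome_features = features, delta = 0.01) {
  sub <- pairwise_subset(cohort, category)
  n_folds <- max(sub$fold) + 1L
  check_fold_classes(sub, n_folds)
  # stratified subcohorts can make a categorical feature single-level
  drop_degenerate <- function(fs) {
    fs[!vapply(fs, function(f) {
      f %in% names(sub) && !is.numeric(sub[[f]]) &&
        length(unique(sub[[f]][!is.na(sub[[f]])])) < 2
    }, logical(1))]
  }
  features <- drop_degenerate(features)
  outcome_features <- drop_degenerate(outcome_features)
  pform <- as.formula(paste("arm ~", if (length(features))
    paste(features, collapse = " + ") else "1"))
  oform <- as.formula(paste("outcome ~ arm",
                            if (length(outcome_features))
                              paste("+", paste(outcome_features, collapse = " + "))
                            else ""))
  res <- vector("list", n_folds)
  train_pids <- vector("list", n_folds)
  for (f in seq_len(n_folds) - 1L) {
    tr <- sub[sub$fold != f, ]
    te <- sub[sub$fold == f, ]
    train_pids[[f + 1L]] <- tr$pid
    # near-separation only inflates coefficients; predictions are clipped
    pfit <- suppressWarnings(glm(pform, data = tr, family = binomial()))
    ofit <- suppressWarnings(glm(oform, data = tr, family = binomial()))
    te1 <- te; te1$arm <- 1L
    te0 <- te; te0$arm <- 0L
    res[[f + 1L]] <- tibble::tibble(
      pid = te$pid, fold = f, arm = te$arm, y = te$outcome,
      g = unname(clip(predict(pfit, newdata = te, type = "response"),
                      delta, 1 - delta)),
      q1 = unname(clip(predict(ofit, newdata = te1, type = "response"),
                       1e-6, 1 - 1e-6)),
      q0 = unname(clip(predict(ofit, newdata = te0, type = "response"),
                       1e-6, 1 - 1e-6)))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "fold_train_pids") <- train_pids
  class(out) <- c("nuisance_estimates", class(out))
  out
}

#' Write / read the JSON-lines nuisance contract
#'
#' One JSON object per line with fields `pid`, `fold`, `arm`, `y`, `g`, `q1`,
#' `q0` — the interface consumed by [cv_tmle_rr()].
#'
#' @param nuisances A `nuisance_estimates` tibble.
#' @param path File path.
#' @return `path` invisibly / the tibble.
#' @export
write_nuisances <- function(nuisances, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(nuisances))) {
    writeLines(jsonlite::toJSON(as.list(nuisances[i, c("pid", "fold", "arm",
                                                       "y", "g", "q1", "q0")]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_nuisances
#' @export
read_nuisances <- function(path) {
  rows <- lapply(readLines(path), function(l)
    tibble::as_tibble(jsonlite::fromJSON(l)))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nuisance_estimates", class(out))
  out
}
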