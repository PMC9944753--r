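# Cohort summary tables and forest-plot-style reporting.

SBP_GROUP_LABELS <- c("<120", "120-129", "130-139", "140-149", "150-159",
                      ">=160")

#' Summarize the built cohort
#'
#' Per-category and overall counts: patients, events, event percentage,
#' censored percentage (patients leaving follow-up without an event), and
#' median follow-up in years. Percentages are `100 * count / n` rounded to
#' one decimal.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param config The [study_config()] (for the follow-up window).
#' @return Tibble with one row per exposure category plus an `all` row.
#' @export
summarize_cohort <- function(cohort, config = study_config()) {
  end_day <- cohort$entry_day + config$followup_end_day
  stop_day <- pmin(ifelse(is.na(cohort$event_day), Inf, cohort$event_day),
                   ifelse(is.na(cohort$censor_day), Inf, cohort$censor_day),
                   end_day)
  fu_years <- (stop_day - cohort$entry_day - config$followup_start_day) /
    DAYS_PER_YEAR
  is_censored <- cohort$outcome == 0 & !is.na(cohort$censor_day)
  one <- function(sel, label) {
    n <- sum(sel)
    n_ev <- sum(cohort$outcome[sel])
    n_cens <- sum(is_censored[sel])
    tibble::tibble(group = label, n = n, events = n_ev,
                   event_pct = cohort_percent(n_ev, n),
                   censored = n_cens,
                   censored_pct = cohort_percent(n_cens, n),
                   median_followup_years = round(median(fu_years[sel]), 2))
  }
  rows <- lapply(0:5, function(cat)
    one(cohort$exposure_cat == cat, SBP_GROUP_LABELS[cat + 1]))
  dplyr::bind_rows(rows, one(rep(TRUE, nrow(cohort)), "all"))
}

#' Assemble a forest table from risk-ratio estimates
#'
#' One row per exposure group and method with events/totals, RR (or HR) and
#' CI. The reference row carries RR 1 with no CI; crude rows carry no CI
#' either (matching the convention that crude and reference estimates are
#' displayed without intervals). A contrast missing for a method yields an
#' explicit `NA` gap row rather than a silent omission.
#'
#' @param estimates List of `rr_estimate` objects (and/or Cox results with
#'   `hr`/`ci_low`/`ci_high`/`contrast`).
#' @param counts Tibble with `category`, `n`, `events` per exposure group
#'   (e.g. `flow$per_category`).
#' @return Tibble with columns `group`, `events`, `total`, `method`, `rr`,
#'   `ci_low`, `ci_high` (fixed column order).
#' @export
render_forest_table <- function(estimates, counts) {
  parse_cat <- function(contrast) as.integer(sub("cat(\\d)_vs_ref", "\\1", contrast))
  rows <- lapply(estimates, function(e) {
    if (!is.null(e$hr)) {
      tibble::tibble(category = parse_cat(e$contrast), method = "cox",
                     rr = e$hr, ci_low = e$ci_low, ci_high = e$ci_high)
    } else {
      tibble::tibble(category = parse_cat(e$contrast), method = e$method,
                     rr = e$rr,
                     ci_low = if (e$method == "crude") NA_real_ else e$ci_low,
                     ci_high = if (e$method == "crude") NA_real_ else e$ci_high)
    }
  })
  est <- dplyr::bind_rows(rows)
  methods <- unique(est$method)
  full <- tidyr::expand_grid(method = methods, category = 0:5) |>
    dplyr::left_join(est, by = c("method", "category")) |>
    dplyr::mutate(rr = ifelse(.data$category == 0, 1, .data$rr),
                  ci_low = ifelse(.data$category == 0, NA_real_, .data$ci_low),
                  ci_high = ifelse(.data$category == 0, NA_real_, .data$ci_high))
  cn <- setNames(counts$n, counts$category)
  ce <- setNames(counts$events, counts$category)
  tibble::tibble(group = SBP_GROUP_LABELS[full$category + 1],
                 events = unname(ce[as.character(full$category)]),
                 total = unname(cn[as.character(full$category)]),
                 method = full$method, rr = full$rr,
                 ci_low = full$ci_low, ci_high = full$ci_high)
}

#' Forest plot of the risk-ratio table
#'
#' @param forest_table Output of [render_forest_table()].
#' @return A ggplot object; the RR axis is logarithmic.
#' @export
plot_forest <- function(forest_table) {
  ft <- forest_table
  ft$group <- factor(ft$group, levels = rev(SBP_GROUP_LABELS))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$rr, y = .data$group,
                                   colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, na.rm = TRUE,
                            position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Risk ratio (log scale)", y = "Baseline SBP (mm Hg)") +
    ggplot2::theme_minimal()
}
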