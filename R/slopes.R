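#' Fit a per-patient eGFR slope
#'
#' Ordinary least-squares fit of eGFR against follow-up time for a single
#' patient. With `window = "full_period"` one line is fitted through all
#' visits; with `window = "between_visits"` a two-point line is fitted to
#' every consecutive visit pair and one row is returned per interval.
#'
#' The annualized percentage slope is `100 * slope / denominator`. The
#' default denominator is the fitted value of the regression line at the
#' start of the window (the intercept at time 0 for the full period; the
#' interval-start fitted value for between-visit intervals), which is robust
#' to baseline measurement noise; `denominator = "observed_baseline"` uses
#' the observed first eGFR value instead, for sensitivity analysis.
#'
#' @param time Visit times in years from baseline (strictly increasing
#'   recommended; at least two distinct values required).
#' @param egfr eGFR values (mL/min/1.73 m^2), same length as `time`.
#' @param window `"full_period"` or `"between_visits"`.
#' @param denominator `"fitted_intercept"` (default) or `"observed_baseline"`.
#' @return A tibble with columns `slope` (mL/min/1.73 m^2 per year),
#'   `intercept` (fitted eGFR at window start), `pct_slope` (%/yr),
#'   `n_points`, `slope_p` (p-value of the regression coefficient; `NA` for
#'   two-point fits) and `window`. For `between_visits`, one row per
#'   consecutive visit pair.
#' @export
fit_egfr_slope <- function(time, egfr,
                           window = c("full_period", "between_visits"),
                           denominator = c("fitted_intercept",
                                           "observed_baseline")) {
  window <- match.arg(window)
  denominator <- match.arg(denominator)
  if (length(time) != length(egfr)) abort("`time` and `egfr` lengths differ")
  ok <- is.finite(time) & is.finite(egfr)
  time <- time[ok]; egfr <- egfr[ok]
  if (length(time) < 2) abort("need at least 2 visits with finite eGFR")
  if (length(unique(time)) < 2) abort("degenerate design: all times identical")
  o <- order(time)
  time <- time[o]; egfr <- egfr[o]

  one_fit <- function(t, y) {
    fit <- lm(y ~ t)
    cf <- unname(stats::coef(fit))
    p <- if (length(y) > 2) {
      suppressWarnings(summary(fit))$coefficients["t", "Pr(>|t|)"]
    } else {
      NA_real_
    }
    # intercept reported at window start (fitted value at min(t))
    start_fit <- cf[1] + cf[2] * t[1]
    denom <- if (denominator == "fitted_intercept") {
      if (identical(t[1], time[1]) && length(y) == length(time)) cf[1] else start_fit
    } else {
      y[1]
    }
    tibble(slope = cf[2],
           intercept = if (length(y) == length(time)) cf[1] else start_fit,
           pct_slope = 100 * cf[2] / denom,
           n_points = length(y), slope_p = p)
  }

  if (window == "full_period") {
    res <- one_fit(time, egfr)
  } else {
    res <- purrr::map_dfr(seq_len(length(time) - 1), function(i) {
      one_fit(time[i:(i + 1)], egfr[i:(i + 1)])
    })
  }
  res$window <- window
  res
}

#' Discovery-cohort kidney function label from a percentage slope
#'
#' Applies the percentage-slope rule set: a loss of more than 10 %/yr is
#' `UNCONTROLLED` (non-response to RAS inhibition), a slope within the
#' closed band \[-5, +5\] %/yr is `CONTROLLED`, and everything else
#' (losing between 5 and 10 %/yr, or gaining more than 5 %/yr) is
#' `EXCLUDED` because it cannot be labeled with confidence. Boundary
#' semantics are literal: -10 exactly is `EXCLUDED`.
#'
#' @param pct_slope Annualized percentage slope(s), %/yr; must be finite.
#' @return Character vector of labels.
#' @export
label_discovery <- function(pct_slope) {
  if (any(!is.finite(pct_slope))) abort("`pct_slope` must be finite")
  dplyr::case_when(
    pct_slope < -10 ~ "UNCONTROLLED",
    pct_slope >= -5 & pct_slope <= 5 ~ "CONTROLLED",
    TRUE ~ "EXCLUDED"
  )
}

#' Validation-cohort kidney function label from absolute eGFR change
#'
#' Applies the stricter absolute rules used for validation cohorts:
#' `UNCONTROLLED` iff the reduction from baseline during follow-up exceeds
#' 10 mL/min/1.73 m^2 *and* some follow-up eGFR drops below 60 (progression
#' to CKD stage 3); `CONTROLLED` iff the total loss is below the cohort
#' threshold (5 or 10 mL/min/1.73 m^2 depending on `cohort_rule`) and eGFR
#' stays above 60 throughout; everything else is `EXCLUDED`.
#'
#' @param baseline Baseline eGFR (single value).
#' @param followups Numeric vector of follow-up eGFR values (non-empty).
#' @param cohort_rule `"loss_lt_5"` or `"loss_lt_10"`: the controlled-group
#'   loss threshold.
#' @param loss_to Reference follow-up for the loss: `"min"` (default, most
#'   sensitive reading) or `"last"`.
#' @return A single label.
#' @export
label_validation <- function(baseline, followups,
                             cohort_rule = c("loss_lt_5", "loss_lt_10"),
                             loss_to = c("min", "last")) {
  cohort_rule <- match.arg(cohort_rule)
  loss_to <- match.arg(loss_to)
  if (length(followups) < 1 || any(!is.finite(followups)) ||
      !is.finite(baseline)) {
    abort("need a finite baseline and at least one finite follow-up eGFR")
  }
  thr <- if (cohort_rule == "loss_lt_5") 5 else 10
  ref <- if (loss_to == "min") min(followups) else followups[length(followups)]
  loss <- baseline - ref
  if (loss > 10 && any(followups < 60)) {
    "UNCONTROLLED"
  } else if (loss < thr && all(c(baseline, followups) > 60)) {
    "CONTROLLED"
  } else {
    "EXCLUDED"
  }
}

#' Label every patient under every eGFR equation
#'
#' Fits per-patient slopes from a visit table that already carries
#' `egfr_<method>` columns (see [add_egfr()]) and assigns kidney function
#' labels. Under the discovery rule set the percentage-slope bands of
#' [label_discovery()] are used; under the validation rule set the absolute
#' change rules of [label_validation()] are applied to the raw eGFR values.
#'
#' @param visits_egfr Visit table with `patient_id`, `time_years` and one
#'   `egfr_<method>` column per method.
#' @param methods eGFR methods to label with (default: all found).
#' @param window Slope window for the discovery rules, see
#'   [fit_egfr_slope()]. The between-visit summary is the arithmetic mean of
#'   the per-interval percentage slopes.
#' @param rule_set `"discovery"` (percentage slopes) or `"validation"`
#'   (absolute changes).
#' @param cohort_rule,loss_to Passed to [label_validation()] when
#'   `rule_set = "validation"`.
#' @param denominator Passed to [fit_egfr_slope()].
#' @return Tibble with `patient_id`, `method`, `window`, `pct_slope`
#'   (`NA` under validation rules), `slope`, `intercept`, `label`. Every
#'   patient receives exactly one label per method.
#' @export
label_patients <- function(visits_egfr, methods = NULL,
                           window = c("full_period", "between_visits"),
                           rule_set = c("discovery", "validation"),
                           cohort_rule = "loss_lt_5", loss_to = "min",
                           denominator = "fitted_intercept") {
  window <- match.arg(window)
  rule_set <- match.arg(rule_set)
  visits_egfr <- as_tibble(visits_egfr)
  found <- sub("^egfr_", "", grep("^egfr_", names(visits_egfr), value = TRUE))
  if (is.null(methods)) methods <- found
  if (!length(methods) || !all(methods %in% found)) {
    abort("requested eGFR method column(s) not present in `visits_egfr`")
  }
  out <- purrr::map_dfr(methods, function(m) {
    col <- paste0("egfr_", m)
    visits_egfr %>%
      group_by(.data$patient_id) %>%
      arrange(.data$time_years, .by_group = TRUE) %>%
      summarise(.fit = list({
        if (rule_set == "discovery") {
          fits <- fit_egfr_slope(.data$time_years, .data[[col]],
                                 window = window, denominator = denominator)
          ps <- mean(fits$pct_slope)
          tibble(pct_slope = ps,
                 slope = mean(fits$slope),
                 intercept = fits$intercept[1],
                 label = label_discovery(ps))
        } else {
          y <- .data[[col]]
          tibble(pct_slope = NA_real_, slope = NA_real_, intercept = y[1],
                 label = label_validation(y[1], y[-1],
                                          cohort_rule = cohort_rule,
                                          loss_to = loss_to))
        }
      }), .groups = "drop") %>%
      tidyr::unnest(".fit") %>%
      mutate(method = m, window = window, .after = "patient_id")
  })
  out
}
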