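#' Rolling baseline creatinine
#'
#' The baseline at time `t` is the lowest measured creatinine over the
#' preceding 7 days, taken over the half-open window `[t - window, t)`:
#' strictly earlier measurements only, so a value is never compared against
#' itself. Returns `NA` when no measurement falls in the window.
#'
#' @param series A data frame with columns `time` (hours from admission) and
#'   `value` (mg/dL), one patient's creatinine measurements.
#' @param t Time (hours) at which to evaluate the baseline.
#' @param window Window width in hours (default 168 = 7 days).
#' @return Baseline creatinine in mg/dL, or `NA_real_` if the window is empty.
#' @export
#' @examples
#' s <- tibble::tibble(time = c(0, 72, 200), value = c(0.9, 1.1, 1.4))
#' rolling_baseline(s, 200) # 1.1: the 0h value has aged out of the window
rolling_baseline <- function(series, t, window = 168) {
  series <- validate_creatinine_series(series)
  if (t < min(series$time)) {
    rlang::abort("t precedes the first measurement in the series")
  }
  window_min(series$time, series$value, t, window)
}

validate_creatinine_series <- function(series) {
  assert_columns(series, c("time", "value"), "creatinine series")
  if (length(series$time) == 0L) rlang::abort("empty creatinine series")
  if (any(!is.finite(series$value)) || any(series$value <= 0)) {
    rlang::abort("creatinine values must be positive and finite")
  }
  # simultaneous duplicates collapse to their maximum (conservative toward
  # detection, and deterministic); sort by time, descending value, keep the
  # first of each timestamp
  o <- order(series$time, -series$value)
  t <- series$time[o]
  v <- series$value[o]
  keep <- !duplicated(t)
  list(time = t[keep], value = v[keep])
}

# Evaluate the KDIGO creatinine trigger at every measurement index of a
# collapsed, sorted series. Returns a list of logical vectors and the
# window minima used, so detection, staging and the sustained flag all share
# one evaluation. Windows are half-open and exclude the current value.
kdigo_trigger_at <- function(times, values, abs_threshold = 0.3,
                             rel_threshold = 1.5, delta_window = 48,
                             baseline_window = 168) {
  n <- length(times)
  dt <- outer(times, times, "-")              # dt[i, j] = t_i - t_j
  prior <- dt > 0
  vmat <- matrix(values, nrow = n, ncol = n, byrow = TRUE)

  min_in <- function(keep) {
    m <- vmat
    m[!keep] <- Inf
    out <- m[cbind(seq_len(n), max.col(-m, ties.method = "first"))]
    out[is.infinite(out)] <- NA_real_
    out
  }
  min48 <- min_in(prior & dt <= delta_window)
  base <- min_in(prior & dt <= baseline_window)

  abs_crit <- !is.na(min48) & (values - min48 >= abs_threshold - CREAT_TOL)
  rel_crit <- !is.na(base) & (values >= rel_threshold * base - CREAT_TOL)
  list(abs_crit = abs_crit, rel_crit = rel_crit, baseline = base)
}

#' Stage an AKI event by the KDIGO creatinine thresholds
#'
#' Stage 3 when the creatinine reaches 3.0 times baseline, or an absolute
#' value of at least 4.0 mg/dL while the onset criteria are met (or renal
#' replacement therapy has been initiated, if an RRT time is supplied by the
#' caller); stage 2 when the ratio is in `[2, 3)`; otherwise stage 1. The
#' ratio boundaries are inclusive at their lower edge.
#'
#' @param value Creatinine at onset (mg/dL).
#' @param baseline Rolling baseline at onset (mg/dL).
#' @param onset_met Logical; whether the KDIGO onset criteria are satisfied
#'   at this measurement (required for the absolute >= 4.0 route).
#' @param rrt Logical; whether renal replacement therapy has been initiated
#'   at or before this time (forces stage 3).
#' @return Integer stage: 1, 2 or 3.
#' @export
stage_aki <- function(value, baseline, onset_met = TRUE, rrt = FALSE) {
  if (!is.finite(value) || !is.finite(baseline) || value <= 0 || baseline <= 0) {
    rlang::abort("stage_aki requires positive finite value and baseline")
  }
  ratio <- value / baseline
  if (rrt || ratio >= 3 - CREAT_TOL || (onset_met && value >= 4 - CREAT_TOL)) {
    return(3L)
  }
  if (ratio >= 2 - CREAT_TOL) return(2L)
  1L
}

#' Detect the first AKI event in a creatinine series
#'
#' Scans an inpatient creatinine series for the earliest measurement at which
#' either KDIGO creatinine criterion fires: an absolute rise of at least
#' `abs_threshold` (default 0.3 mg/dL) above the minimum value in the
#' preceding `delta_window` hours (default 48), or a value at least
#' `rel_threshold` (default 1.5) times the rolling baseline (the minimum over
#' the preceding `baseline_window` hours, default 168). Onset requires at
#' least one strictly earlier measurement — AKI cannot be declared on the
#' first value — and only the first event per admission is reported; later
#' time points are censored by downstream modules.
#'
#' @inheritParams rolling_baseline
#' @param abs_threshold Absolute rise threshold (mg/dL) within `delta_window`.
#' @param rel_threshold Relative threshold versus rolling baseline.
#' @param delta_window,baseline_window Window widths in hours.
#' @return A one-row tibble (`onset_time`, `stage`, `criterion`,
#'   `baseline_at_onset`, `value_at_onset`, `sustained`) or `NULL` when no
#'   event is detected. `criterion` is one of `"absolute_rise_48h"`,
#'   `"relative_rise_baseline"`, `"both"`.
#' @export
#' @examples
#' detect_aki(tibble::tibble(time = c(0, 24), value = c(1.0, 1.3)))
detect_aki <- function(series, abs_threshold = 0.3, rel_threshold = 1.5,
                       delta_window = 48, baseline_window = 168) {
  series <- validate_creatinine_series(series)
  n <- length(series$time)
  if (n < 2L) return(NULL)

  trig <- kdigo_trigger_at(series$time, series$value,
                           abs_threshold = abs_threshold,
                           rel_threshold = rel_threshold,
                           delta_window = delta_window,
                           baseline_window = baseline_window)
  fired <- trig$abs_crit | trig$rel_crit
  if (!any(fired)) return(NULL)
  i <- which(fired)[1L]

  criterion <- if (trig$abs_crit[i] && trig$rel_crit[i]) {
    "both"
  } else if (trig$abs_crit[i]) {
    "absolute_rise_48h"
  } else {
    "relative_rise_baseline"
  }

  # whenever a criterion fires there is a prior value within 168h, so the
  # baseline is always defined at onset
  baseline <- trig$baseline[i]
  stage <- stage_aki(series$value[i], baseline, onset_met = TRUE)
  sustained <- if (i < n) (trig$abs_crit[i + 1L] || trig$rel_crit[i + 1L]) else FALSE

  tibble::tibble(
    onset_time = series$time[i],
    stage = stage,
    criterion = criterion,
    baseline_at_onset = baseline,
    value_at_onset = series$value[i],
    sustained = sustained
  )
}

#' Flag sustained AKI
#'
#' Sustained AKI requires at least two consecutive creatinine values
#' consistent with an AKI diagnosis: the onset measurement and the next
#' measurement in time must each satisfy the KDIGO trigger, each evaluated
#' against its own windows. An onset with no later measurement is not
#' sustained.
#'
#' @inheritParams detect_aki
#' @param event A detected event as returned by [detect_aki()].
#' @return Logical.
#' @export
flag_sustained <- function(series, event, abs_threshold = 0.3,
                           rel_threshold = 1.5, delta_window = 48,
                           baseline_window = 168) {
  series <- validate_creatinine_series(series)
  i <- match(event$onset_time, series$time)
  if (is.na(i)) rlang::abort("event onset_time is not a series timestamp")
  if (i >= length(series$time)) return(FALSE)
  trig <- kdigo_trigger_at(series$time, series$value,
                           abs_threshold = abs_threshold,
                           rel_threshold = rel_threshold,
                           delta_window = delta_window,
                           baseline_window = baseline_window)
  trig$abs_crit[i + 1L] || trig$rel_crit[i + 1L]
}

#' Detect AKI events across a measurement table
#'
#' Applies [detect_aki()] to every patient's creatinine series in a long
#' measurement table and returns one row per patient with a detected event.
#'
#' @param measurements Long table with columns `patient_id`, `time_hours`,
#'   `analyte`, `value`; only `analyte == "creatinine"` rows are used.
#' @inheritParams detect_aki
#' @return Tibble with `patient_id`, `onset_time`, `stage`, `criterion`,
#'   `baseline_at_onset`, `value_at_onset`, `sustained`; zero rows when no
#'   patient has an event.
#' @export
detect_aki_events <- function(measurements, abs_threshold = 0.3,
                              rel_threshold = 1.5, delta_window = 48,
                              baseline_window = 168) {
  assert_columns(measurements, c("patient_id", "time_hours", "analyte", "value"),
                 "measurement table")
  creat <- measurements %>%
    dplyr::filter(.data$analyte == "creatinine") %>%
    dplyr::select(patient_id = "patient_id", time = "time_hours",
                  value = "value")
  if (nrow(creat) == 0L) {
    return(tibble::tibble(patient_id = character(), onset_time = double(),
                          stage = integer(), criterion = character(),
                          baseline_at_onset = double(),
                          value_at_onset = double(), sustained = logical()))
  }
  creat %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::group_modify(function(df, key) {
      ev <- detect_aki(df, abs_threshold = abs_threshold,
                       rel_threshold = rel_threshold,
                       delta_window = delta_window,
                       baseline_window = baseline_window)
      if (is.null(ev)) ev <- tibble::tibble()
      ev
    }) %>%
    dplyr::ungroup()
}
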