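# Discrete-time observation matrix: one row per covariate update, with
# last-observation-carried-forward state, derived creatinine features,
# post-onset censoring and 24h-lookahead labels.

#' Build the discrete-time observation rows
#'
#' Emits one observation row per distinct event timestamp (a lab measurement
#' or an exposure onset) per patient, mimicking a live EHR in which a new
#' prediction is generated each time a covariate value is updated.
#' Time-varying covariates are carried forward from their latest measurement;
#' simultaneous events collapse into a single row with all updates applied.
#' Three creatinine features are derived at each row: `last_creatinine`
#' (latest measured value, including one at the row's own timestamp),
#' `baseline_creatinine` (minimum over the preceding `baseline_window` hours,
#' strictly before the row time), and `delta_creatinine_48h` (last creatinine
#' minus the minimum measured value in the preceding `delta_window` hours; 0
#' when no prior value falls in that window). Rows before the first
#' creatinine measurement carry a missing creatinine state. Rows at or after
#' a patient's detected AKI onset are never emitted.
#'
#' @param patients Patient table (must contain `patient_id` and the
#'   demographic covariates of [covariate_spec()]).
#' @param measurements Long measurement table (`patient_id`, `time_hours`,
#'   `analyte`, `value`), sorted by time within patient.
#' @param exposures Long exposure table (`patient_id`, `time_hours`,
#'   `exposure`); exposures are absorbing.
#' @param events Detected AKI events as from [detect_aki_events()], or `NULL`.
#' @param baseline_window,delta_window Window widths in hours.
#' @return A tibble with `patient_id`, `time_hours` and one column per
#'   covariate in [covariate_spec()]; `NA` encodes a missing (never measured)
#'   value.
#' @export
build_rows <- function(patients, measurements, exposures = NULL,
                       events = NULL, baseline_window = 168,
                       delta_window = 48) {
  assert_columns(patients, c("patient_id", covariates_for_class("demographic")),
                 "patient table")
  assert_columns(measurements, c("patient_id", "time_hours", "analyte", "value"),
                 "measurement table")
  unsorted <- measurements %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(bad = is.unsorted(.data$time_hours), .groups = "drop")
  if (any(unsorted$bad)) {
    rlang::abort("measurements must be sorted by time within patient")
  }
  if (is.null(exposures)) {
    exposures <- tibble::tibble(patient_id = character(),
                                time_hours = double(), exposure = character())
  }
  measurements <- dplyr::semi_join(measurements, patients, by = "patient_id")
  exposures <- dplyr::semi_join(exposures, patients, by = "patient_id")

  skeleton <- dplyr::bind_rows(
    dplyr::select(measurements, "patient_id", "time_hours"),
    dplyr::select(exposures, "patient_id", "time_hours")
  ) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$patient_id, .data$time_hours)

  # carried-forward labs (simultaneous duplicates collapse to the maximum)
  other_labs <- setdiff(lab_analytes(), "creatinine")
  lab_wide <- measurements %>%
    tidyr::pivot_wider(id_cols = c("patient_id", "time_hours"),
                       names_from = "analyte", values_from = "value",
                       values_fn = max)
  for (a in c(other_labs, "creatinine")) {
    if (!a %in% names(lab_wide)) lab_wide[[a]] <- NA_real_
  }
  rows <- skeleton %>%
    dplyr::left_join(lab_wide, by = c("patient_id", "time_hours")) %>%
    dplyr::group_by(.data$patient_id) %>%
    tidyr::fill(dplyr::all_of(c(other_labs, "creatinine")),
                .direction = "down") %>%
    dplyr::ungroup() %>%
    dplyr::rename(last_creatinine = "creatinine")

  # windowed creatinine features against the measured series
  creat <- measurements %>%
    dplyr::filter(.data$analyte == "creatinine") %>%
    dplyr::group_by(.data$patient_id, .data$time_hours) %>%
    dplyr::summarise(value = max(.data$value), .groups = "drop")
  creat_by_pat <- split(creat[c("time_hours", "value")], creat$patient_id)
  win_feats <- function(pid, rt) {
    s <- creat_by_pat[[pid]]
    if (is.null(s)) {
      return(list(base = rep(NA_real_, length(rt)),
                  min48 = rep(NA_real_, length(rt))))
    }
    dt <- outer(rt, s$time_hours, "-")
    vm <- matrix(s$value, nrow = length(rt), ncol = nrow(s), byrow = TRUE)
    min_in <- function(keep) {
      m <- vm
      m[!keep] <- Inf
      out <- m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
      out[is.infinite(out)] <- NA_real_
      out
    }
    list(base = min_in(dt > 0 & dt <= baseline_window),
         min48 = min_in(dt > 0 & dt <= delta_window))
  }
  feats <- rows %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::group_map(function(df, key) {
      f <- win_feats(key$patient_id[[1]], df$time_hours)
      tibble::tibble(baseline_creatinine = f$base, min48 = f$min48)
    }) %>%
    dplyr::bind_rows()
  rows$baseline_creatinine <- feats$baseline_creatinine
  rows$delta_creatinine_48h <- dplyr::if_else(
    is.na(rows$last_creatinine), NA_real_,
    dplyr::coalesce(rows$last_creatinine - feats$min48, 0))

  # absorbing exposure indicators
  expo_first <- if (nrow(exposures)) {
    exposures %>%
      dplyr::group_by(.data$patient_id, .data$exposure) %>%
      dplyr::summarise(on = min(.data$time_hours), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "exposure", values_from = "on")
  } else {
    tibble::tibble(patient_id = character())
  }
  rows <- dplyr::left_join(rows, expo_first, by = "patient_id")
  for (e in exposure_names()) {
    if (!e %in% names(rows)) rows[[e]] <- NA_real_
    rows[[e]] <- as.integer(!is.na(rows[[e]]) & rows$time_hours >= rows[[e]])
  }

  rows <- dplyr::left_join(
    rows,
    dplyr::select(patients, "patient_id",
                  dplyr::all_of(covariates_for_class("demographic"))),
    by = "patient_id")

  # censor at detected onset: rows at or after onset are never emitted
  if (!is.null(events) && nrow(events)) {
    rows <- rows %>%
      dplyr::left_join(dplyr::select(events, "patient_id", "onset_time"),
                       by = "patient_id") %>%
      dplyr::filter(is.na(.data$onset_time) |
                      .data$time_hours < .data$onset_time) %>%
      dplyr::select(-"onset_time")
  }

  dplyr::select(rows, "patient_id", "time_hours",
                dplyr::all_of(covariate_spec()$name))
}

#' Attach lookahead outcome labels to observation rows
#'
#' A row is labeled positive for an outcome iff the outcome time falls in
#' the half-open window `(time, time + horizon]`: a row exactly at the event
#' is censored (the onset measurement itself already shows the rise), while
#' a row exactly `horizon` hours before is positive. The same machinery
#' produces the AKI, sustained-AKI, renal-replacement-therapy and death
#' labels; patient-level "any during admission" indicator columns are also
#' attached for cohort summaries.
#'
#' @param rows Observation rows from [build_rows()].
#' @param events Detected AKI events (`patient_id`, `onset_time`,
#'   `sustained`), or `NULL` for none.
#' @param outcomes Optional patient-level outcome times (`patient_id`,
#'   `rrt_hours`, `death_hours`).
#' @param horizon Lookahead in hours (default 24).
#' @return `rows` with columns `label_aki_24h`, `label_sustained_aki_24h`,
#'   `label_rrt_24h`, `label_death_24h`, `any_aki`, `any_sustained_aki`,
#'   `any_rrt`, `any_death`. Label column names always use the `_24h` suffix
#'   style regardless of `horizon`.
#' @export
label_rows <- function(rows, events = NULL, outcomes = NULL, horizon = 24) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    rlang::abort("horizon must be a single positive number of hours")
  }
  assert_columns(rows, c("patient_id", "time_hours"), "observation rows")

  lookup_time <- function(tbl, col) {
    if (is.null(tbl) || !nrow(tbl) || !col %in% names(tbl)) {
      return(rep(NA_real_, nrow(rows)))
    }
    tbl[[col]][match(rows$patient_id, tbl$patient_id)]
  }
  in_window <- function(t_event) {
    as.integer(!is.na(t_event) & t_event > rows$time_hours &
                 t_event <= rows$time_hours + horizon)
  }

  onset <- lookup_time(events, "onset_time")
  sus_events <- if (!is.null(events) && nrow(events)) {
    events[events$sustained, , drop = FALSE]
  } else {
    NULL
  }
  sus_onset <- lookup_time(sus_events, "onset_time")
  rrt <- lookup_time(outcomes, "rrt_hours")
  death <- lookup_time(outcomes, "death_hours")

  rows$label_aki_24h <- in_window(onset)
  rows$label_sustained_aki_24h <- in_window(sus_onset)
  rows$label_rrt_24h <- in_window(rrt)
  rows$label_death_24h <- in_window(death)
  rows$any_aki <- as.integer(!is.na(onset))
  rows$any_sustained_aki <- as.integer(!is.na(sus_onset))
  rows$any_rrt <- as.integer(!is.na(rrt))
  rows$any_death <- as.integer(!is.na(death))
  rows
}

#' Complete-case filter for a covariate class
#'
#' Missing data are never imputed: a model class only scores rows on which
#' every covariate it requires has been observed. Demographic covariates are
#' always complete, so the demographic class drops nothing.
#'
#' @param rows Labeled observation rows.
#' @param class One of [model_classes()].
#' @return The filtered rows, with attribute `dropped_fraction`.
#' @export
complete_case_filter <- function(rows, class) {
  required <- covariates_for_class(class)
  assert_columns(rows, required, "observation rows")
  keep <- stats::complete.cases(rows[required])
  out <- rows[keep, , drop = FALSE]
  attr(out, "dropped_fraction") <- if (nrow(rows)) 1 - mean(keep) else 0
  out
}

#' Patient-level train/validation split
#'
#' Randomly assigns patients of the internal hospital to training and
#' validation partitions at the requested fractions; patients of any other
#' hospital pass through untouched as external-validation strata. The split
#' is always at the patient level — all of a patient's rows share one
#' partition — and is deterministic under the seed.
#'
#' @param patients Patient table (`patient_id`, optionally `hospital`).
#' @param fractions Named fractions `c(train = , validation = )` summing to 1.
#' @param seed Integer seed.
#' @param internal_hospital Hospital id whose patients are split (default
#'   `"A"`); ignored when there is no `hospital` column (all patients are
#'   then internal).
#' @return Tibble `patient_id`, `partition` (`"train"`, `"validation"`, or
#'   `"external_<hospital>"`).
#' @export
split_cohort <- function(patients, fractions = c(train = 2 / 3, validation = 1 / 3),
                         seed = 1L, internal_hospital = "A") {
  if (length(fractions) != 2L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    rlang::abort("fractions must be two non-negative numbers summing to 1")
  }
  assert_columns(patients, "patient_id", "patient table")
  internal <- if ("hospital" %in% names(patients)) {
    patients$hospital == internal_hospital
  } else {
    rep(TRUE, nrow(patients))
  }
  ids <- patients$patient_id[internal]
  n_train <- round(fractions[[1]] * length(ids))
  train_ids <- withr::with_seed(seed, sample(ids, n_train))
  partition <- dplyr::if_else(
    internal,
    dplyr::if_else(patients$patient_id %in% train_ids, "train", "validation"),
    paste0("external_", if ("hospital" %in% names(patients)) {
      patients$hospital
    } else {
      ""
    })
  )
  tibble::tibble(patient_id = patients$patient_id, partition = partition)
}
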