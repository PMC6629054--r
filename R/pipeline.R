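# Pipeline driver and file interchange. CSV with ISO-8601 timestamps is the
# interchange format; internally all times are real-valued hours from
# admission.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. The clinical defaults
#' are the study constants: a 24-hour prediction horizon, a 168-hour (7-day)
#' rolling-baseline window, a 48-hour delta window, a 0.3 mg/dL absolute
#' rise threshold and a 1.5-fold relative threshold.
#'
#' @param sim A [sim_config()] describing the cohort to simulate, or `NULL`
#'   when tables are supplied to [run_pipeline()] directly.
#' @param horizon_hours Lookahead for the outcome labels (> 0).
#' @param baseline_window_hours,delta_window_hours KDIGO window widths.
#' @param abs_threshold_mg_dl,rel_threshold KDIGO trigger thresholds.
#' @param split_fractions Named train/validation fractions summing to 1.
#' @param split_seed,eval_seed Seeds for the patient split and the bootstrap.
#' @param bootstrap_b Bootstrap replicates for AUC intervals.
#' @param classes Covariate classes to fit (subset of [model_classes()]).
#' @param outcomes Outcomes to model (`aki24`, `sustained_aki24`, `rrt`,
#'   `death`).
#' @param refit_per_outcome If `TRUE` (default) a model is refit for every
#'   outcome; if `FALSE` the `aki24` fit is re-scored against the other
#'   outcomes' labels.
#' @param eval_strata Partitions to evaluate (default `NULL`: every
#'   non-training partition). Restrict this when small external strata carry
#'   no events of a rare outcome.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL,
                            horizon_hours = 24,
                            baseline_window_hours = 168,
                            delta_window_hours = 48,
                            abs_threshold_mg_dl = 0.3,
                            rel_threshold = 1.5,
                            split_fractions = c(train = 2 / 3, validation = 1 / 3),
                            split_seed = 1L,
                            eval_seed = 1L,
                            bootstrap_b = 2000L,
                            classes = model_classes(),
                            outcomes = "aki24",
                            refit_per_outcome = TRUE,
                            eval_strata = NULL) {
  assert_scalar_number(horizon_hours, "horizon_hours", positive = TRUE)
  assert_scalar_number(baseline_window_hours, "baseline_window_hours",
                       positive = TRUE)
  assert_scalar_number(delta_window_hours, "delta_window_hours",
                       positive = TRUE)
  assert_scalar_number(abs_threshold_mg_dl, "abs_threshold_mg_dl",
                       positive = TRUE)
  assert_scalar_number(rel_threshold, "rel_threshold", positive = TRUE)
  if (length(split_fractions) != 2L || any(split_fractions < 0) ||
      abs(sum(split_fractions) - 1) > 1e-8) {
    stop_field("split_fractions", "must be two fractions summing to 1")
  }
  bad <- setdiff(classes, model_classes())
  if (length(bad)) stop_field("classes", paste0("unknown: ",
                                                paste(bad, collapse = ", ")))
  bad <- setdiff(outcomes, c("aki24", "sustained_aki24", "rrt", "death"))
  if (length(bad)) stop_field("outcomes", paste0("unknown: ",
                                                 paste(bad, collapse = ", ")))
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    stop_field("sim", "must be a sim_config or NULL")
  }
  structure(list(
    sim = sim, horizon_hours = horizon_hours,
    baseline_window_hours = baseline_window_hours,
    delta_window_hours = delta_window_hours,
    abs_threshold_mg_dl = abs_threshold_mg_dl,
    rel_threshold = rel_threshold,
    split_fractions = split_fractions,
    split_seed = as.integer(split_seed), eval_seed = as.integer(eval_seed),
    bootstrap_b = as.integer(bootstrap_b),
    classes = classes, outcomes = outcomes,
    refit_per_outcome = isTRUE(refit_per_outcome),
    eval_strata = eval_strata
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains simulate (optional) -> exclusions -> KDIGO labeling -> observation
#' rows -> lookahead labels -> patient split -> per-class model fits ->
#' clustered evaluation grid, and assembles a manifest (configuration,
#' seeds, per-stage row/patient counts, software version) from which the
#' whole run is re-derivable. Any stage failure aborts with a stage-named
#' error.
#'
#' @param config A [pipeline_config()].
#' @param cohort An `aki_cohort` (or a list with `patients`, `measurements`,
#'   `exposures` and optionally `ground_truth`); when `NULL`, one is
#'   simulated from `config$sim`.
#' @param out_dir Optional directory; when given, the input tables, the
#'   observation matrix, the evaluation grid and the manifest (JSON) are
#'   written there.
#' @return A list of class `aki_pipeline_result`: `manifest`,
#'   `exclusion_report`, `events`, `rows`, `fits`, `grid`.
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  if (is.null(cohort)) {
    if (is.null(config$sim)) {
      rlang::abort("pipeline stage 'simulate' failed: no cohort and no sim config")
    }
    cohort <- stage("simulate", generate_cohort(config$sim))
  }
  for (tbl in c("patients", "measurements", "exposures")) {
    if (is.null(cohort[[tbl]])) {
      rlang::abort(sprintf("pipeline stage 'input' failed: missing table '%s'",
                           tbl))
    }
  }

  excl <- stage("filter", apply_exclusions(cohort$patients, cohort$measurements))
  events <- stage("label", detect_aki_events(
    cohort$measurements,
    abs_threshold = config$abs_threshold_mg_dl,
    rel_threshold = config$rel_threshold,
    delta_window = config$delta_window_hours,
    baseline_window = config$baseline_window_hours))
  events <- dplyr::semi_join(events, excl$patients, by = "patient_id")

  outcome_times <- cohort$ground_truth$patients %||%
    tibble::tibble(patient_id = character(), rrt_hours = double(),
                   death_hours = double())
  rows <- stage("build", {
    r <- build_rows(excl$patients, cohort$measurements, cohort$exposures,
                    events, baseline_window = config$baseline_window_hours,
                    delta_window = config$delta_window_hours)
    label_rows(r, events, outcome_times, horizon = config$horizon_hours)
  })

  split <- stage("split", split_cohort(excl$patients,
                                       fractions = config$split_fractions,
                                       seed = config$split_seed))
  rows <- dplyr::left_join(rows, split, by = "patient_id")

  fits <- stage("fit", {
    specs <- if (config$refit_per_outcome) {
      tidyr::expand_grid(class = config$classes, outcome = config$outcomes)
    } else {
      tibble::tibble(class = config$classes, outcome = "aki24")
    }
    purrr::pmap(specs, function(class, outcome) {
      fit_discrete_logit(rows[rows$partition == "train", , drop = FALSE],
                         class, outcome)
    })
  })

  grid <- stage("evaluate", {
    eval_fits <- fits
    if (!config$refit_per_outcome && length(config$outcomes) > 1L) {
      # re-score the aki24 fits against the other outcomes' labels
      eval_fits <- purrr::flatten(purrr::map(fits, function(f) {
        purrr::map(config$outcomes, function(o) {
          f$outcome_tag <- o
          f
        })
      }))
    }
    evaluation_grid(eval_fits, rows, strata = config$eval_strata,
                    B = config$bootstrap_b, seed = config$eval_seed)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("akiward")),
    config = unclass(config[setdiff(names(config), "sim")]),
    sim_config = if (!is.null(config$sim)) unclass(config$sim),
    counts = list(
      n_input_patients = nrow(cohort$patients),
      n_included_patients = nrow(excl$patients),
      n_measurements = nrow(cohort$measurements),
      n_exposure_events = nrow(cohort$exposures),
      n_aki_events = nrow(events),
      n_observation_rows = nrow(rows),
      exclusions = as.list(excl$report)
    )
  )

  result <- structure(list(manifest = manifest, exclusion_report = excl$report,
                           events = events, rows = rows, fits = fits,
                           grid = grid),
                      class = "aki_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, out_dir)
    readr::write_csv(rows, file.path(out_dir, "matrix.csv"))
    readr::write_csv(dplyr::select(grid, -"roc"),
                     file.path(out_dir, "evaluation_grid.csv"))
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$input_hashes <- as.list(tools::md5sum(files))
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' @export
print.aki_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<aki_pipeline_result> %d included patients, %d AKI events, %d rows, %d fits\n",
    x$manifest$counts$n_included_patients, x$manifest$counts$n_aki_events,
    x$manifest$counts$n_observation_rows, length(x$fits)))
  print(x$grid, n = 20)
  invisible(x)
}

#' Write a cohort's tables to CSV with ISO-8601 timestamps
#'
#' Event times (internally hours from admission) are written as calendar
#' timestamps (UTC, ISO-8601) anchored at each patient's admission time;
#' [read_cohort_csv()] inverts the conversion.
#'
#' @param cohort An `aki_cohort` or compatible list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  admit <- cohort$patients$admit_time[match(cohort$measurements$patient_id,
                                            cohort$patients$patient_id)]
  meas <- cohort$measurements %>%
    dplyr::mutate(timestamp = format(admit + .data$time_hours * 3600,
                                     "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) %>%
    dplyr::select("patient_id", "timestamp", "analyte", "value")
  admit_e <- cohort$patients$admit_time[match(cohort$exposures$patient_id,
                                              cohort$patients$patient_id)]
  expo <- cohort$exposures %>%
    dplyr::mutate(timestamp = format(admit_e + .data$time_hours * 3600,
                                     "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) %>%
    dplyr::select("patient_id", "timestamp", "exposure")
  pats <- cohort$patients %>%
    dplyr::mutate(
      admit_time = format(.data$admit_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      discharge_time = ifelse(is.na(.data$discharge_time), NA_character_,
                              format(.data$discharge_time,
                                     "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  paths <- file.path(dir, c("patients.csv", "measurements.csv",
                            "exposures.csv"))
  readr::write_csv(pats, paths[1], na = "")
  readr::write_csv(meas, paths[2], na = "")
  readr::write_csv(expo, paths[3], na = "")
  if (!is.null(cohort$ground_truth)) {
    gt <- file.path(dir, "ground_truth.csv")
    readr::write_csv(cohort$ground_truth$patients, gt, na = "")
    paths <- c(paths, gt)
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `patients.csv`, `measurements.csv`,
#'   `exposures.csv` (and optionally `ground_truth.csv`).
#' @return A list with `patients`, `measurements`, `exposures` (times as
#'   hours from admission) and, when present, `ground_truth$patients`.
#' @export
read_cohort_csv <- function(dir) {
  parse_iso <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC")
  pats <- readr::read_csv(file.path(dir, "patients.csv"),
                          show_col_types = FALSE) %>%
    dplyr::mutate(admit_time = parse_iso(.data$admit_time),
                  discharge_time = parse_iso(.data$discharge_time))
  to_hours <- function(df) {
    admit <- pats$admit_time[match(df$patient_id, pats$patient_id)]
    df %>%
      dplyr::mutate(time_hours = as.numeric(difftime(parse_iso(.data$timestamp),
                                                     admit, units = "hours"))) %>%
      dplyr::select(-"timestamp")
  }
  meas <- to_hours(readr::read_csv(file.path(dir, "measurements.csv"),
                                   show_col_types = FALSE)) %>%
    dplyr::select("patient_id", "time_hours", "analyte", "value") %>%
    dplyr::arrange(.data$patient_id, .data$time_hours, .data$analyte)
  expo <- to_hours(readr::read_csv(file.path(dir, "exposures.csv"),
                                   show_col_types = FALSE)) %>%
    dplyr::select("patient_id", "time_hours", "exposure") %>%
    dplyr::arrange(.data$patient_id, .data$time_hours)
  out <- list(patients = pats, measurements = meas, exposures = expo)
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    out$ground_truth <- list(patients = readr::read_csv(gt_path,
                                                        show_col_types = FALSE))
  }
  out
}
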