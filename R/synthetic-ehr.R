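# Synthetic inpatient EHR generator. Emulates the longitudinal structure the
# analysis assumes — irregular lab panels, absorbing medication/procedure
# exposures, episodic creatinine rises — with AKI onsets drawn from a known
# discrete-time logistic hazard so downstream stages can be validated against
# ground truth.

# population lab distributions: patient-level mean ~ N(mean, between_sd),
# measurement = patient mean + N(0, within_sd); creatinine is lognormal
lab_population <- function() {
  tibble::tibble(
    analyte    = c("bicarbonate", "bun", "chloride", "hemoglobin",
                   "potassium", "sodium", "wbc", "platelets"),
    mean       = c(24, 18, 102, 11.5, 4.1, 138, 9, 230),
    between_sd = c(2.5, 7, 3.5, 1.8, 0.35, 3, 3, 70),
    within_sd  = c(1.2, 2.5, 1.5, 0.5, 0.2, 1.2, 1.2, 20)
  )
}

default_exposure_prevalences <- function() {
  c(ace_arb = 0.25, antibiotic = 0.45, chemotherapy = 0.03, diuretic = 0.30,
    narcotic = 0.40, nsaid = 0.15, vasopressor = 0.08, ppi = 0.35,
    statin = 0.30, bipap = 0.05, contrast = 0.15, ventilation = 0.07,
    icu = 0.12, cardiac_cath = 0.04, rbc_transfusion = 0.08)
}

default_hazard_coefficients <- function() {
  c(age = 0.015, diabetes = 0.35, chf = 0.30, elixhauser = 0.08,
    vasopressor = 0.8, diuretic = 0.4, nsaid = 0.25, icu = 0.6,
    bun = 0.02, bicarbonate = -0.06)
}

#' Configuration for the synthetic EHR generator
#'
#' Bundles and validates every knob of the generator. The defaults emulate a
#' general inpatient population: median length of stay around 4-5 days,
#' roughly 1.5 lab panels per day, a lognormal baseline creatinine centred
#' near 0.9 mg/dL, a per-6-hour discrete logistic AKI hazard tuned so that
#' close to one in five patients develops AKI during the admission, and three
#' hospitals with modest intercept heterogeneity. A small share of patients
#' is generated deliberately exclusion-eligible (missing discharge time, an
#' end-stage kidney disease code, fewer than two creatinine values, admission
#' creatinine at or above 4 mg/dL) so the cohort filter has work to do.
#'
#' @param n_patients Number of hospitalizations to simulate (>= 1).
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @param mean_los_hours Mean length of stay in hours (gamma-distributed,
#'   truncated to 24-480 h).
#' @param lab_rate_per_day Poisson intensity of lab-panel draws per day; every
#'   panel measures all nine analytes.
#' @param baseline_creat_log_mean,baseline_creat_log_sd Log-scale mean and sd
#'   of the per-patient baseline creatinine (mg/dL).
#' @param hazard_intercept Intercept of the discrete-time logistic hazard, in
#'   log-odds of AKI onset per `tick_hours` interval.
#' @param hazard_coefficients Named numeric vector of log-odds-per-unit
#'   effects; names may be demographic covariates, exposure names, or lab
#'   analytes (whose true state is the last drawn value, carried forward).
#' @param aki_rise_slope Post-onset creatinine escalation, mg/dL per 24 h.
#' @param aki_rise_duration Hours over which the rise continues before
#'   plateauing.
#' @param exposure_prevalences Named probabilities of each absorbing exposure;
#'   an exposed patient acquires the exposure at a uniform time and keeps it.
#' @param hospital_proportions Named probabilities of hospital membership.
#' @param hospital_effects Named per-hospital shifts added to the hazard
#'   intercept (per-hospital AKI incidence heterogeneity); `NULL` for none.
#' @param tick_hours Grid step (hours) on which the generative hazard is
#'   evaluated.
#' @param frac_missing_discharge,frac_eskd,frac_sparse_creatinine,frac_admission_creat_ge4
#'   Fractions of patients generated exclusion-eligible under each rule.
#' @param death_prob_no_aki,death_prob_aki Probability of inpatient death
#'   without / with AKI.
#' @param rrt_prob_aki Probability an AKI patient receives renal replacement
#'   therapy.
#' @param creat_noise_sd Measurement noise sd for creatinine (mg/dL).
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 1)
sim_config <- function(n_patients,
                       seed = 1L,
                       mean_los_hours = 120,
                       lab_rate_per_day = 1.5,
                       baseline_creat_log_mean = log(0.9),
                       baseline_creat_log_sd = 0.25,
                       hazard_intercept = -5.0,
                       hazard_coefficients = default_hazard_coefficients(),
                       aki_rise_slope = 0.8,
                       aki_rise_duration = 72,
                       exposure_prevalences = default_exposure_prevalences(),
                       hospital_proportions = c(A = 0.6, B = 0.2, C = 0.2),
                       hospital_effects = c(A = 0, B = 0.15, C = -0.15),
                       tick_hours = 6,
                       frac_missing_discharge = 0.02,
                       frac_eskd = 0.02,
                       frac_sparse_creatinine = 0.03,
                       frac_admission_creat_ge4 = 0.01,
                       death_prob_no_aki = 0.02,
                       death_prob_aki = 0.10,
                       rrt_prob_aki = 0.08,
                       creat_noise_sd = 0.06) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      !is.finite(n_patients) || n_patients < 1) {
    stop_field("n_patients", "must be a single integer >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_field("seed", "must be a single integer")
  }
  assert_scalar_number(mean_los_hours, "mean_los_hours", positive = TRUE)
  assert_scalar_number(lab_rate_per_day, "lab_rate_per_day", positive = TRUE)
  assert_scalar_number(baseline_creat_log_mean, "baseline_creat_log_mean")
  assert_scalar_number(baseline_creat_log_sd, "baseline_creat_log_sd",
                       positive = TRUE)
  assert_scalar_number(hazard_intercept, "hazard_intercept")
  assert_scalar_number(aki_rise_slope, "aki_rise_slope", positive = TRUE)
  assert_scalar_number(aki_rise_duration, "aki_rise_duration", positive = TRUE)
  assert_scalar_number(tick_hours, "tick_hours", positive = TRUE)
  assert_scalar_number(creat_noise_sd, "creat_noise_sd", positive = TRUE)
  if (length(hazard_coefficients) &&
      (is.null(names(hazard_coefficients)) ||
       any(!nzchar(names(hazard_coefficients))))) {
    stop_field("hazard_coefficients", "must be a named numeric vector")
  }
  known <- c(covariates_for_class("demographic"),
             setdiff(lab_analytes(), "creatinine"), exposure_names())
  unknown <- setdiff(names(hazard_coefficients), known)
  if (length(unknown)) {
    stop_field("hazard_coefficients",
               paste0("names not simulated: ", paste(unknown, collapse = ", ")))
  }
  assert_prob(exposure_prevalences, "exposure_prevalences")
  unknown <- setdiff(names(exposure_prevalences), exposure_names())
  if (length(unknown)) {
    stop_field("exposure_prevalences",
               paste0("unknown exposures: ", paste(unknown, collapse = ", ")))
  }
  assert_prob(hospital_proportions, "hospital_proportions")
  if (abs(sum(hospital_proportions) - 1) > 1e-8) {
    stop_field("hospital_proportions", "must sum to 1")
  }
  if (!is.null(hospital_effects) &&
      !all(names(hospital_proportions) %in% names(hospital_effects))) {
    stop_field("hospital_effects", "must cover every hospital")
  }
  for (f in c("frac_missing_discharge", "frac_eskd", "frac_sparse_creatinine",
              "frac_admission_creat_ge4", "death_prob_no_aki",
              "death_prob_aki", "rrt_prob_aki")) {
    assert_prob(get(f), f)
  }

  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    mean_los_hours = mean_los_hours, lab_rate_per_day = lab_rate_per_day,
    baseline_creat_log_mean = baseline_creat_log_mean,
    baseline_creat_log_sd = baseline_creat_log_sd,
    hazard_intercept = hazard_intercept,
    hazard_coefficients = hazard_coefficients,
    aki_rise_slope = aki_rise_slope, aki_rise_duration = aki_rise_duration,
    exposure_prevalences = exposure_prevalences,
    hospital_proportions = hospital_proportions,
    hospital_effects = hospital_effects,
    tick_hours = tick_hours,
    frac_missing_discharge = frac_missing_discharge,
    frac_eskd = frac_eskd,
    frac_sparse_creatinine = frac_sparse_creatinine,
    frac_admission_creat_ge4 = frac_admission_creat_ge4,
    death_prob_no_aki = death_prob_no_aki,
    death_prob_aki = death_prob_aki,
    rrt_prob_aki = rrt_prob_aki,
    creat_noise_sd = creat_noise_sd
  ), class = "sim_config")
}

# ---- internal simulation stages (all assume the RNG is already seeded) ----

sim_patients <- function(config) {
  n <- config$n_patients
  hosp <- sample(names(config$hospital_proportions), n, replace = TRUE,
                 prob = config$hospital_proportions)
  los <- pmin(pmax(rgamma(n, shape = 2, scale = config$mean_los_hours / 2),
                   24), 480)

  # mutually exclusive exclusion arms, assigned by one multinomial draw
  arm_probs <- c(none = 1 - config$frac_missing_discharge - config$frac_eskd -
                   config$frac_sparse_creatinine -
                   config$frac_admission_creat_ge4,
                 missing_discharge = config$frac_missing_discharge,
                 eskd = config$frac_eskd,
                 sparse_creatinine = config$frac_sparse_creatinine,
                 high_admission_creat = config$frac_admission_creat_ge4)
  if (arm_probs[["none"]] < 0) {
    stop_field("frac_*", "exclusion-arm fractions must sum to <= 1")
  }
  arm <- sample(names(arm_probs), n, replace = TRUE, prob = arm_probs)

  creat_mean <- rlnorm(n, config$baseline_creat_log_mean,
                       config$baseline_creat_log_sd)
  creat_mean[arm == "high_admission_creat"] <-
    runif(sum(arm == "high_admission_creat"), 4.2, 5.5)

  admit <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC") +
    floor(runif(n, 0, 365 * 24)) * 3600

  patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    hospital = hosp,
    admit_time = admit,
    discharge_time = admit + round(los) * 3600,
    los_hours = los,
    age = pmin(pmax(round(rnorm(n, 66, 16)), 18), 100),
    sex_male = rbinom(n, 1, 0.47),
    race_black = rbinom(n, 1, 0.18),
    surgical = rbinom(n, 1, 0.26),
    chf = rbinom(n, 1, 0.15),
    hypertension = rbinom(n, 1, 0.45),
    diabetes = rbinom(n, 1, 0.22),
    liver_disease = rbinom(n, 1, 0.06),
    elixhauser = rpois(n, 3),
    eskd = arm == "eskd",
    sim_arm = arm,
    creat_mean = creat_mean
  )
  patients$discharge_time[arm == "missing_discharge"] <- as.POSIXct(NA)

  # per-patient latent lab means for the eight non-creatinine analytes
  pop <- lab_population()
  means <- purrr::map(seq_len(nrow(pop)), function(i) {
    pmax(rnorm(n, pop$mean[i], pop$between_sd[i]), pop$mean[i] / 10)
  })
  names(means) <- pop$analyte
  lab_means <- tibble::as_tibble(means)
  lab_means$patient_id <- patients$patient_id
  lab_means$creatinine <- creat_mean

  list(patients = patients, lab_means = lab_means)
}

sim_exposures <- function(patients, config) {
  prev <- config$exposure_prevalences
  if (!length(prev)) {
    return(tibble::tibble(patient_id = character(), time_hours = double(),
                          exposure = character()))
  }
  n <- nrow(patients)
  purrr::imap(prev, function(p, nm) {
    exposed <- which(runif(n) < p)
    tibble::tibble(
      patient_id = patients$patient_id[exposed],
      time_hours = runif(length(exposed), 0, patients$los_hours[exposed]),
      exposure = nm
    )
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::arrange(.data$patient_id, .data$time_hours)
}

# lab-panel draws: every panel measures the requested analytes at one time
sim_measurements <- function(patients, lab_means, config,
                             analytes = lab_analytes()) {
  n <- nrow(patients)
  n_extra <- rpois(n, config$lab_rate_per_day * patients$los_hours / 24)
  n_extra[patients$sim_arm == "sparse_creatinine"] <- 0L

  first_time <- runif(n, 0.5, 2)
  extra <- tibble::tibble(
    patient_id = rep(patients$patient_id, n_extra),
    los = rep(patients$los_hours, n_extra)
  )
  extra$time_hours <- runif(nrow(extra), 2, pmax(extra$los - 0.5, 2.5))
  panel_times <- dplyr::bind_rows(
    tibble::tibble(patient_id = patients$patient_id, time_hours = first_time),
    dplyr::select(extra, "patient_id", "time_hours")
  )

  pop <- lab_population()
  out <- purrr::map(analytes, function(a) {
    m <- panel_times
    m$analyte <- a
    mu <- lab_means[[a]][match(m$patient_id, lab_means$patient_id)]
    sd_w <- if (a == "creatinine") config$creat_noise_sd else
      pop$within_sd[pop$analyte == a]
    m$value <- mu + rnorm(nrow(m), 0, sd_w)
    floor_v <- if (a == "creatinine") 0.1 else mu / 20
    m$value <- pmax(m$value, floor_v)
    m
  }) %>% dplyr::bind_rows()

  out %>% dplyr::arrange(.data$patient_id, .data$time_hours, .data$analyte)
}

# evaluate the discrete-time hazard on the tick grid and draw onsets.
# Lab covariate truth = last drawn value carried forward (the patient's
# latent mean before the first draw); exposures are absorbing indicators.
sim_hazard <- function(patients, lab_means, measurements, exposures, config) {
  coefs <- config$hazard_coefficients
  tick <- config$tick_hours
  n_ticks <- pmax(floor(patients$los_hours / tick), 0L)

  rows <- tibble::tibble(
    patient_id = rep(patients$patient_id, n_ticks),
    time_hours = sequence(n_ticks) * tick
  )
  if (nrow(rows) == 0L) {
    return(list(rows = rows, onsets = tibble::tibble(patient_id = character(),
                                                     true_onset_hours = double())))
  }

  demo_names <- intersect(names(coefs), covariates_for_class("demographic"))
  lab_names <- intersect(names(coefs), lab_analytes())
  expo_names <- intersect(names(coefs), exposure_names())

  if (length(demo_names)) {
    rows <- dplyr::left_join(
      rows, dplyr::select(patients, "patient_id", dplyr::all_of(demo_names)),
      by = "patient_id")
  }
  if (length(lab_names)) {
    upd <- measurements %>%
      dplyr::filter(.data$analyte %in% lab_names) %>%
      tidyr::pivot_wider(id_cols = c("patient_id", "time_hours"),
                         names_from = "analyte", values_from = "value",
                         values_fn = max)
    grid <- dplyr::bind_rows(
      dplyr::mutate(upd, .is_tick = FALSE),
      dplyr::mutate(rows[c("patient_id", "time_hours")], .is_tick = TRUE)
    ) %>%
      dplyr::arrange(.data$patient_id, .data$time_hours, .data$.is_tick) %>%
      dplyr::group_by(.data$patient_id) %>%
      tidyr::fill(dplyr::all_of(lab_names), .direction = "down") %>%
      dplyr::ungroup() %>%
      dplyr::filter(.data$.is_tick)
    for (a in lab_names) {
      mu <- lab_means[[a]][match(grid$patient_id, lab_means$patient_id)]
      grid[[a]] <- dplyr::coalesce(grid[[a]], mu)
    }
    rows <- dplyr::left_join(
      rows, dplyr::select(grid, "patient_id", "time_hours",
                          dplyr::all_of(lab_names)),
      by = c("patient_id", "time_hours"))
  }
  if (length(expo_names)) {
    onset_tbl <- exposures %>%
      dplyr::filter(.data$exposure %in% expo_names) %>%
      dplyr::group_by(.data$patient_id, .data$exposure) %>%
      dplyr::summarise(expo_on = min(.data$time_hours), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "exposure", values_from = "expo_on")
    for (e in setdiff(expo_names, names(onset_tbl))) onset_tbl[[e]] <- NA_real_
    rows <- dplyr::left_join(rows, onset_tbl, by = "patient_id")
    for (e in expo_names) {
      rows[[e]] <- as.integer(!is.na(rows[[e]]) & rows$time_hours >= rows[[e]])
    }
  }

  eta <- rep(config$hazard_intercept, nrow(rows))
  if (!is.null(config$hospital_effects)) {
    hosp <- patients$hospital[match(rows$patient_id, patients$patient_id)]
    eta <- eta + unname(config$hospital_effects[hosp])
  }
  for (nm in names(coefs)) eta <- eta + coefs[[nm]] * rows[[nm]]
  rows$true_prob <- plogis(eta)

  rows$.hit <- runif(nrow(rows)) < rows$true_prob
  rows <- rows %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::mutate(.hits_before = cumsum(.data$.hit) - .data$.hit) %>%
    dplyr::ungroup()
  rows$event <- as.integer(rows$.hit & rows$.hits_before == 0L)
  rows <- rows %>%
    dplyr::filter(.data$.hits_before == 0L) %>%
    dplyr::select(-".hits_before", -".hit")

  onsets <- rows %>%
    dplyr::filter(.data$event == 1L) %>%
    dplyr::select("patient_id", true_onset_hours = "time_hours")
  list(rows = rows, onsets = onsets)
}

#' Simulate discrete-time hazard rows with ground truth
#'
#' Runs the generator up to (and including) the hazard stage and returns the
#' tick-level truth: one row per patient per hazard interval up to and
#' including the onset interval, with the true covariate state, the true
#' per-interval event probability, and the realized event indicator. Fitting
#' a patient-clustered logistic regression to these rows is the canonical
#' parameter-recovery check of the generator/model pair.
#'
#' @param config A [sim_config()].
#' @return A list with `rows` (tibble: `patient_id`, `time_hours`, hazard
#'   covariates, `true_prob`, `event`), `onsets` (tibble: `patient_id`,
#'   `true_onset_hours`), and `coefficients` (the generative truth, intercept
#'   first).
#' @export
simulate_hazard_rows <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    ps <- sim_patients(config)
    expo <- sim_exposures(ps$patients, config)
    lab_needed <- intersect(names(config$hazard_coefficients), lab_analytes())
    meas <- if (length(lab_needed)) {
      sim_measurements(ps$patients, ps$lab_means, config, analytes = lab_needed)
    } else {
      tibble::tibble(patient_id = character(), time_hours = double(),
                     analyte = character(), value = double())
    }
    hz <- sim_hazard(ps$patients, ps$lab_means, meas, expo, config)
  })
  hz$coefficients <- c("(Intercept)" = config$hazard_intercept,
                       config$hazard_coefficients)
  hz
}

#' Generate a synthetic hospital cohort
#'
#' Produces the three event tables the analysis consumes — a patient table,
#' a long timed-measurement table, and a timed-exposure table — plus ground
#' truth. AKI onsets are drawn from the configured discrete-time logistic
#' hazard evaluated on the true covariate state; after onset the patient's
#' creatinine climbs linearly (`aki_rise_slope` mg/dL per 24 h for
#' `aki_rise_duration` hours, then plateaus) so the KDIGO engine can
#' rediscover the onset from the measured series. A follow-up creatinine
#' draw is scheduled shortly after onset, mimicking clinical rechecking.
#' Inpatient death and renal replacement therapy times are drawn with
#' AKI-dependent probabilities.
#'
#' @param config A [sim_config()].
#' @return An object of class `aki_cohort`: a list with `patients`,
#'   `measurements`, `exposures` tibbles and `ground_truth` (list of
#'   `patients` — true onset / death / RRT hours —, `rows` — tick-level
#'   hazard truth —, and `coefficients`).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 30, seed = 7))
#' names(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  res <- withr::with_seed(config$seed, {
    ps <- sim_patients(config)
    patients <- ps$patients
    expo <- sim_exposures(patients, config)
    meas <- sim_measurements(patients, ps$lab_means, config)
    hz <- sim_hazard(patients, ps$lab_means, meas, expo, config)

    onset <- hz$onsets$true_onset_hours[match(patients$patient_id,
                                              hz$onsets$patient_id)]

    # post-onset creatinine escalation on already-drawn panels
    is_creat <- meas$analyte == "creatinine"
    m_on <- onset[match(meas$patient_id, patients$patient_id)]
    rise_rows <- which(is_creat & !is.na(m_on) & meas$time_hours > m_on)
    if (length(rise_rows)) {
      dt <- pmin(meas$time_hours[rise_rows] - m_on[rise_rows],
                 config$aki_rise_duration)
      base <- ps$lab_means$creatinine[match(meas$patient_id[rise_rows],
                                            ps$lab_means$patient_id)]
      meas$value[rise_rows] <- pmax(
        base + config$aki_rise_slope * dt / 24 +
          rnorm(length(rise_rows), 0, config$creat_noise_sd), 0.1)
    }

    # recheck creatinine draw after onset, if it fits in the stay
    aki_idx <- which(!is.na(onset))
    if (length(aki_idx)) {
      recheck_t <- onset[aki_idx] + runif(length(aki_idx), 6, 24)
      keep <- recheck_t < patients$los_hours[aki_idx]
      if (any(keep)) {
        idx <- aki_idx[keep]
        dt <- pmin(recheck_t[keep] - onset[idx], config$aki_rise_duration)
        base <- ps$lab_means$creatinine[match(patients$patient_id[idx],
                                              ps$lab_means$patient_id)]
        meas <- dplyr::bind_rows(meas, tibble::tibble(
          patient_id = patients$patient_id[idx],
          time_hours = recheck_t[keep],
          analyte = "creatinine",
          value = pmax(base + config$aki_rise_slope * dt / 24 +
                         rnorm(sum(keep), 0, config$creat_noise_sd), 0.1)
        ))
      }
    }
    meas <- dplyr::arrange(meas, .data$patient_id, .data$time_hours,
                           .data$analyte)

    # inpatient death and RRT, AKI-dependent
    n <- nrow(patients)
    has_aki <- !is.na(onset)
    p_death <- ifelse(has_aki, config$death_prob_aki, config$death_prob_no_aki)
    dies <- runif(n) < p_death
    death_hours <- rep(NA_real_, n)
    lo <- ifelse(has_aki, onset + 12, 24)
    lo <- pmin(lo, patients$los_hours - 1)
    death_hours[dies] <- runif(sum(dies), lo[dies], patients$los_hours[dies])

    rrt_hours <- rep(NA_real_, n)
    gets_rrt <- has_aki & runif(n) < config$rrt_prob_aki
    if (any(gets_rrt)) {
      rt <- onset[gets_rrt] + runif(sum(gets_rrt), 24, 96)
      rt <- pmin(rt, patients$los_hours[gets_rrt] - 0.5)
      ok <- rt > onset[gets_rrt]
      rrt_hours[which(gets_rrt)[ok]] <- rt[ok]
    }

    gt_patients <- tibble::tibble(
      patient_id = patients$patient_id,
      true_onset_hours = onset,
      death_hours = death_hours,
      rrt_hours = rrt_hours
    )
    list(patients = dplyr::select(patients, -"creat_mean"),
         measurements = meas,
         exposures = expo,
         ground_truth = list(
           patients = gt_patients,
           rows = hz$rows,
           coefficients = c("(Intercept)" = config$hazard_intercept,
                            config$hazard_coefficients)))
  })
  structure(res, class = "aki_cohort", config = config)
}

#' @export
print.aki_cohort <- function(x, ...) {
  n_aki <- sum(!is.na(x$ground_truth$patients$true_onset_hours))
  cat(sprintf(
    "<aki_cohort> %d patients, %d measurements, %d exposure events; %d true AKI onsets (%.1f%%)\n",
    nrow(x$patients), nrow(x$measurements), nrow(x$exposures),
    n_aki, 100 * n_aki / nrow(x$patients)))
  invisible(x)
}

#' Remove a fraction of non-creatinine lab measurements
#'
#' Emulates laboratory missingness by deleting each non-creatinine lab row
#' independently with probability `rate`. Creatinine rows are never removed:
#' the outcome must remain ascertainable from the measured series.
#'
#' @param measurements Long measurement table (`patient_id`, `time_hours`,
#'   `analyte`, `value`).
#' @param rate Removal probability in `[0, 1]`.
#' @param seed Integer seed; deletion is deterministic given the seed.
#' @return The thinned measurement table.
#' @export
inject_missingness <- function(measurements, rate, seed = 1L) {
  assert_columns(measurements, c("patient_id", "time_hours", "analyte", "value"),
                 "measurement table")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate < 0 || rate > 1) {
    rlang::abort("rate must be a single probability in [0, 1]")
  }
  eligible <- measurements$analyte != "creatinine"
  drop <- withr::with_seed(seed, runif(nrow(measurements)) < rate) & eligible
  measurements[!drop, , drop = FALSE]
}
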