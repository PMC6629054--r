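test_that("one row per event timestamp, with carry-forward state", {
  pats <- make_patients("p1")
  m <- tibble::tibble(
    patient_id = "p1",
    time_hours = c(0, 6, 24),
    analyte = c("creatinine", "sodium", "creatinine"),
    value = c(1.0, 140, 1.1)
  )
  rows <- build_rows(pats, m)
  expect_equal(rows$time_hours, c(0, 6, 24))
  expect_true(is.na(rows$sodium[1])) # sodium not yet measured at 0h
  expect_equal(rows$last_creatinine[2], 1.0) # carried forward to the 6h row
  expect_equal(rows$sodium[2], 140)
  expect_equal(rows$sodium[3], 140)
  expect_equal(rows$last_creatinine[3], 1.1)
})

test_that("rows at or after AKI onset are never emitted", {
  pats <- make_patients("p1")
  m <- tibble::tibble(
    patient_id = "p1", time_hours = c(10, 20, 30, 40),
    analyte = "creatinine", value = c(1.0, 1.05, 1.4, 1.6)
  )
  ev <- detect_aki_events(m)
  expect_equal(ev$onset_time, 30)
  rows <- build_rows(pats, m, events = ev)
  expect_equal(rows$time_hours, c(10, 20))
})

test_that("carried-forward cells match a brute-force latest-value scan", {
  cohort <- make_cohort(60, seed = 31)
  kept <- apply_exclusions(cohort$patients, cohort$measurements)$patients
  rows <- build_rows(kept, cohort$measurements, cohort$exposures)
  m <- cohort$measurements
  check <- rows[sample.int(nrow(rows), min(400, nrow(rows))), ]
  for (a in setdiff(lab_analytes(), "creatinine")) {
    for (i in seq_len(nrow(check))) {
      sub <- m[m$patient_id == check$patient_id[i] & m$analyte == a, ]
      expect_equal(check[[a]][i],
                   oracle_locf(sub$time_hours, sub$value, check$time_hours[i]))
    }
  }
  # last_creatinine uses the same carry-forward rule
  for (i in seq_len(min(200, nrow(check)))) {
    sub <- m[m$patient_id == check$patient_id[i] &
               m$analyte == "creatinine", ]
    sub <- dplyr::summarise(dplyr::group_by(sub, .data$time_hours),
                            value = max(.data$value), .groups = "drop")
    expect_equal(check$last_creatinine[i],
                 oracle_locf(sub$time_hours, sub$value, check$time_hours[i]))
  }
})

test_that("the 48h creatinine delta re-derives from the raw series", {
  cohort <- make_cohort(50, seed = 33)
  kept <- apply_exclusions(cohort$patients, cohort$measurements)$patients
  rows <- build_rows(kept, cohort$measurements, cohort$exposures)
  m <- cohort$measurements[cohort$measurements$analyte == "creatinine", ]
  for (i in seq_len(nrow(rows))) {
    sub <- m[m$patient_id == rows$patient_id[i], ]
    t <- rows$time_hours[i]
    w <- sub$value[sub$time_hours > t - 48 & sub$time_hours < t]
    last <- oracle_locf(sub$time_hours, pmax(sub$value, sub$value), t)
    expected <- if (is.na(rows$last_creatinine[i])) {
      NA_real_
    } else if (length(w)) {
      rows$last_creatinine[i] - min(w)
    } else {
      0
    }
    expect_equal(rows$delta_creatinine_48h[i], expected)
  }
})

test_that("exposures are absorbing and create observation rows", {
  pats <- make_patients("p1")
  m <- tibble::tibble(patient_id = "p1", time_hours = c(0, 48),
                      analyte = "creatinine", value = c(1.0, 1.0))
  e <- tibble::tibble(patient_id = "p1", time_hours = 12,
                      exposure = "diuretic")
  rows <- build_rows(pats, m, e)
  expect_equal(rows$time_hours, c(0, 12, 48))
  expect_equal(rows$diuretic, c(0L, 1L, 1L))
  expect_equal(rows$nsaid, c(0L, 0L, 0L))
})

test_that("lookahead labels use the half-open (t, t + 24] window", {
  pats <- make_patients("p1")
  m <- tibble::tibble(patient_id = "p1", time_hours = c(5, 6, 10, 29),
                      analyte = "creatinine", value = c(1.0, 1.0, 1.0, 1.0))
  rows <- build_rows(pats, m)
  ev <- tibble::tibble(patient_id = "p1", onset_time = 30, sustained = FALSE)
  lab <- label_rows(rows, ev)
  expect_equal(lab$label_aki_24h[lab$time_hours == 10], 1L) # gap 20h <= 24h
  expect_equal(lab$label_aki_24h[lab$time_hours == 5], 0L)  # gap 25h > 24h
  expect_equal(lab$label_aki_24h[lab$time_hours == 6], 1L)  # exactly 24h before
  expect_equal(lab$label_aki_24h[lab$time_hours == 29], 1L)

  no_event <- label_rows(rows, NULL)
  expect_true(all(no_event$label_aki_24h == 0))
  expect_true(all(no_event$label_rrt_24h == 0))

  expect_error(label_rows(rows, ev, horizon = -1), "horizon")
})

test_that("sustained, RRT and death labels share the lookahead machinery", {
  pats <- make_patients("p1")
  m <- tibble::tibble(patient_id = "p1", time_hours = c(0, 10, 20),
                      analyte = "creatinine", value = c(1.0, 1.0, 1.0))
  rows <- build_rows(pats, m)
  ev <- tibble::tibble(patient_id = "p1", onset_time = 30, sustained = TRUE)
  out <- tibble::tibble(patient_id = "p1", rrt_hours = 40, death_hours = 90)
  lab <- label_rows(rows, ev, out)
  expect_equal(lab$label_sustained_aki_24h, c(0L, 1L, 1L))
  expect_equal(lab$label_rrt_24h, c(0L, 0L, 1L))
  expect_equal(lab$label_death_24h, c(0L, 0L, 0L))
  expect_true(all(lab$any_death == 1L))
})

test_that("complete-case filtering drops rows per required class only", {
  pats <- make_patients("p1")
  m <- tibble::tibble(
    patient_id = "p1", time_hours = c(0, 0, 6),
    analyte = c("creatinine", "sodium", "creatinine"),
    value = c(1.0, 140, 1.05)
  )
  rows <- label_rows(build_rows(pats, m), NULL)
  # every lab except sodium/creatinine is missing -> laboratory class drops all
  expect_equal(nrow(complete_case_filter(rows, "laboratory")), 0L)
  kept <- complete_case_filter(rows, "demographic")
  expect_equal(nrow(kept), nrow(rows))
  expect_equal(attr(kept, "dropped_fraction"), 0)
  expect_error(complete_case_filter(rows, "vitals"), "unknown covariate class")
})

test_that("dropped fraction equals brute-force enumeration under injected missingness", {
  cohort <- make_cohort(120, seed = 35)
  meas <- inject_missingness(cohort$measurements, 0.25, seed = 2)
  kept <- apply_exclusions(cohort$patients, meas)$patients
  rows <- label_rows(build_rows(kept, meas, cohort$exposures), NULL)
  required <- covariates_for_class("laboratory")
  manual <- vapply(seq_len(nrow(rows)), function(i) {
    any(vapply(required, function(v) is.na(rows[[v]][i]), TRUE))
  }, TRUE)
  filtered <- complete_case_filter(rows, "laboratory")
  expect_equal(nrow(filtered), sum(!manual))
  expect_equal(attr(filtered, "dropped_fraction"), mean(manual))
  expect_gt(mean(manual), 0)
})

test_that("the patient split is exact, deterministic and patient-level", {
  pats <- make_patients(sprintf("p%02d", 1:9))
  s1 <- split_cohort(pats, seed = 7)
  expect_equal(sum(s1$partition == "train"), 6L)
  expect_equal(sum(s1$partition == "validation"), 3L)
  expect_identical(s1, split_cohort(pats, seed = 7))

  cohort <- make_cohort(200, seed = 36)
  s <- split_cohort(cohort$patients, seed = 3)
  expect_true(all(table(s$patient_id) == 1))
  ext <- cohort$patients$hospital != "A"
  expect_true(all(s$partition[ext] ==
                    paste0("external_", cohort$patients$hospital[ext])))
  expect_true(all(s$partition[!ext] %in% c("train", "validation")))

  expect_error(split_cohort(pats, fractions = c(0.5, 0.4)), "summing to 1")
})

test_that("unsorted measurements are rejected", {
  pats <- make_patients("p1")
  m <- tibble::tibble(patient_id = "p1", time_hours = c(10, 0),
                      analyte = "creatinine", value = c(1, 1))
  expect_error(build_rows(pats, m), "sorted")
})
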