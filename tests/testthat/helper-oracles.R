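# Independent brute-force oracles. These deliberately share no code with the
# package: per-index scans instead of matrix tricks, literal translations of
# the clinical rules.

# O(n^2) KDIGO detector: for each measurement index, scan all prior values
# for the 48h minimum and the 7-day baseline, apply both criteria, return
# the first firing index with criterion, stage and sustained flag.
oracle_detect_aki <- function(time, value, abs_threshold = 0.3,
                              rel_threshold = 1.5, delta_window = 48,
                              baseline_window = 168, tol = 1e-9) {
  o <- order(time, -value)
  time <- time[o]
  value <- value[o]
  keep <- !duplicated(time)
  time <- time[keep]
  value <- value[keep]
  n <- length(time)
  if (n < 2) return(NULL)

  fires <- function(i) {
    prior48 <- value[time < time[i] & time >= time[i] - delta_window]
    prior7d <- value[time < time[i] & time >= time[i] - baseline_window]
    abs_ok <- length(prior48) > 0 &&
      value[i] - min(prior48) >= abs_threshold - tol
    rel_ok <- length(prior7d) > 0 &&
      value[i] >= rel_threshold * min(prior7d) - tol
    list(abs = abs_ok, rel = rel_ok,
         base = if (length(prior7d)) min(prior7d) else NA_real_)
  }
  for (i in 2:n) {
    f <- fires(i)
    if (f$abs || f$rel) {
      ratio <- value[i] / f$base
      stage <- if (ratio >= 3 - tol || value[i] >= 4 - tol) {
        3L
      } else if (ratio >= 2 - tol) {
        2L
      } else {
        1L
      }
      sustained <- FALSE
      if (i < n) {
        f2 <- fires(i + 1)
        sustained <- f2$abs || f2$rel
      }
      return(list(onset_time = time[i],
                  criterion = if (f$abs && f$rel) "both" else
                    if (f$abs) "absolute_rise_48h" else "relative_rise_baseline",
                  stage = stage, sustained = sustained))
    }
  }
  NULL
}

# brute-force "latest value at or before t" scan
oracle_locf <- function(times, values, t) {
  at_or_before <- which(times <= t)
  if (!length(at_or_before)) return(NA_real_)
  values[at_or_before[which.max(times[at_or_before])]]
}

# pairwise AUC: concordant pairs count 1, ties 0.5
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random creatinine series: lengths 2-50, values 0.3-8.0 mg/dL, spacings
# 1-72h, occasional duplicated timestamps
fuzz_series <- function(n_series, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_series), function(i) {
      n <- sample(2:50, 1)
      gaps <- runif(n - 1, 1, 72)
      time <- cumsum(c(0, gaps))
      if (n > 3 && runif(1) < 0.15) {
        j <- sample(2:n, 1)
        time[j] <- time[j - 1]
      }
      list(time = time, value = round(runif(n, 0.3, 8.0), 2))
    })
  })
}

# hand-built patient table with complete demographics
make_patients <- function(ids, los = 96) {
  admit <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")
  tibble::tibble(
    patient_id = ids, hospital = "A",
    admit_time = admit, discharge_time = admit + los * 3600,
    los_hours = los,
    age = 60, sex_male = 1, race_black = 0, surgical = 0, chf = 0,
    hypertension = 1, diabetes = 0, liver_disease = 0, elixhauser = 2,
    eskd = FALSE
  )
}

# small labeled cohort built through the package generator
make_cohort <- function(n_patients, seed, ...) {
  generate_cohort(sim_config(n_patients = n_patients, seed = seed, ...))
}
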