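test_that("midrank AUC matches hand-enumerated pairs", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(c(1, 2), c(1, 1)), "positive and.*negative")
  expect_error(auc(c(1), c(1, 0)), "equal length")
})

test_that("AUC equals brute-force pair counting on fuzzed inputs", {
  withr::with_seed(91, {
    for (r in 1:150) {
      n <- sample(5:120, 1)
      scores <- round(runif(n), sample(c(1, 2, 6), 1)) # force ties sometimes
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) %in% c(0, n)) next
      expect_equal(auc(scores, labels), oracle_auc(scores, labels))
    }
  })
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(92, {
    scores <- rnorm(200)
    labels <- rbinom(200, 1, 0.3)
    a0 <- auc(scores, labels)
    expect_equal(auc(exp(scores), labels), a0)
    expect_equal(auc(qlogis(plogis(scores)), labels), a0, tolerance = 1e-12)
    expect_equal(auc(rank(scores, ties.method = "average"), labels), a0)
  })
})

test_that("ROC points form a monotone staircase whose area is the AUC", {
  withr::with_seed(93, {
    scores <- round(runif(300), 2)
    labels <- rbinom(300, 1, 0.3)
    roc <- roc_points(scores, labels)
    expect_equal(roc$sensitivity[1], 0)
    expect_equal(roc$specificity[1], 1)
    expect_equal(roc$sensitivity[nrow(roc)], 1)
    expect_equal(roc$specificity[nrow(roc)], 0)
    expect_true(all(diff(roc$sensitivity) >= 0))
    expect_true(all(diff(roc$specificity) <= 0))
    x <- 1 - roc$specificity
    y <- roc$sensitivity
    trap <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
    expect_equal(trap, auc(scores, labels), tolerance = 1e-12)
  })
})

test_that("patient-bootstrap CI is seed-stable and near the DeLong interval", {
  skip_if_not_installed("pROC")
  withr::with_seed(94, {
    n <- 300
    labels <- rbinom(n, 1, 0.3)
    scores <- rnorm(n, mean = labels) # AUC ~ 0.76
  })
  ids <- sprintf("p%03d", seq_along(scores)) # one row per patient
  ev <- clustered_auc_ci(scores, labels, ids, B = 2000, seed = 5)
  ev2 <- clustered_auc_ci(scores, labels, ids, B = 2000, seed = 5)
  expect_equal(ev$ci_low, ev2$ci_low)
  expect_equal(ev$ci_high, ev2$ci_high)

  dl <- suppressMessages(pROC::ci.auc(labels, scores, method = "delong"))
  boot_width <- ev$ci_high - ev$ci_low
  delong_width <- dl[3] - dl[1]
  expect_lt(abs(boot_width - delong_width) / delong_width, 0.2)
  expect_equal(ev$auc, as.numeric(dl[2]), tolerance = 1e-12)
})

test_that("degenerate bootstrap data raise an informative error", {
  # two single-class patients: exactly half of all resamples are single-class
  expect_error(
    clustered_auc_ci(c(0.9, 0.1), c(1, 0), c("p1", "p2"), B = 100, seed = 1),
    "degenerate")
  expect_error(clustered_auc_ci(1:4, c(1, 0, 0, 1), paste0("p", 1:4), B = 10),
               "at least 100")
  # a mildly sparse case still succeeds, with redraws counted
  ev <- clustered_auc_ci(c(0.9, 0.1, 0.2, 0.3), c(1, 0, 0, 0),
                         paste0("p", 1:4), B = 100, seed = 1)
  expect_gt(ev$n_redraws, 0)
})

test_that("PPV arithmetic matches the worked operating points", {
  expect_equal(ppv_at_operating_point(0.80, 0.50, 0.15)$ppv,
               0.12 / (0.12 + 0.425), tolerance = 1e-12)
  expect_equal(ppv_at_operating_point(0.375, 0.875, 0.15)$ppv_percent, 35)
  expect_equal(ppv_at_operating_point(0.6, 1, 0.15)$ppv, 1) # no false positives
  expect_error(ppv_at_operating_point(0, 0.5, 0.15), "sensitivity")
  expect_error(ppv_at_operating_point(0.5, 0.5, 1.5), "prevalence")
})

test_that("operating points honor targets from the feasible side", {
  # perfect classifier: sensitivity target met at specificity 1
  roc <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  op <- operating_point(roc, sensitivity = 0.8)
  expect_equal(op$specificity, 1.0)

  withr::with_seed(95, {
    scores <- runif(4000)
    labels <- rbinom(4000, 1, 0.3)
  })
  roc <- roc_points(scores, labels)
  op <- operating_point(roc, sensitivity = 0.8)
  expect_equal(op$specificity, 0.2, tolerance = 0.08) # null model: spec ~ 1 - sens

  # brute-force scan over all thresholds agrees
  target <- 0.65
  feas <- roc[roc$sensitivity >= target, ]
  best <- feas[order(feas$sensitivity - target, -feas$specificity), ][1, ]
  op2 <- operating_point(roc, sensitivity = target)
  expect_equal(op2$threshold, best$threshold)
  expect_equal(op2$sensitivity, best$sensitivity)
  expect_equal(op2$specificity, best$specificity)

  expect_error(operating_point(roc[0, ], sensitivity = 0.5), "empty")
  expect_error(operating_point(roc), "exactly one")
})

test_that("evaluation grid covers 0.5 for a pure-noise class and names bad cells", {
  cohort <- make_cohort(500, seed = 61,
                        hazard_coefficients = c(age = 0.02, bun = 0.04),
                        hazard_intercept = -5.5)
  kept <- apply_exclusions(cohort$patients, cohort$measurements)$patients
  ev <- detect_aki_events(cohort$measurements)
  rows <- label_rows(build_rows(kept, cohort$measurements, cohort$exposures, ev),
                     ev, cohort$ground_truth$patients)
  rows <- dplyr::left_join(rows, split_cohort(kept, seed = 2), by = "patient_id")

  # medications are noise here: an exposure-free hazard drives the outcome
  fit <- fit_discrete_logit(rows[rows$partition == "train", ], "medications")
  grid <- evaluation_grid(list(fit), rows, strata = "validation",
                          B = 400, seed = 3)
  expect_equal(nrow(grid), 1L)
  expect_true(grid$ci_low < 0.5 + 0.12 & grid$ci_high > 0.5 - 0.12)
  expect_s3_class(grid$roc[[1]], "tbl_df")

  rows2 <- rows
  rows2$label_aki_24h <- 0L
  expect_error(evaluation_grid(list(fit), rows2, strata = "validation",
                               B = 400, seed = 3),
               "class=medications.*stratum=validation")
})
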