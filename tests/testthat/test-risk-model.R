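sim_rows <- function(n, beta, seed, rows_per_patient = 1) {
  withr::with_seed(seed, {
    p <- ncol <- length(beta) - 1
    n_pat <- n %/% rows_per_patient
    pid <- rep(sprintf("p%05d", seq_len(n_pat)), each = rows_per_patient)
    X <- matrix(rnorm(length(pid) * p), ncol = p)
    eta <- beta[1] + drop(X %*% beta[-1])
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- paste0("x", seq_len(p))
    df$patient_id <- pid
    df$y <- rbinom(length(pid), 1, plogis(eta))
    df
  })
}

test_that("intercept-only fit returns the exact log-odds of prevalence", {
  df <- tibble::tibble(patient_id = sprintf("p%03d", 1:100),
                       y = rep(c(1L, 0L), c(25, 75)))
  fit <- fit_cluster_logit(df, "y", character(0))
  expect_equal(unname(fit$coefficients[1]), log(25 / 75), tolerance = 1e-8)
  expect_equal(export_closed_form(fit),
               sprintf("logit(p) = %.17g", fit$coefficients[[1]]))
})

test_that("coefficients agree with glm and the sandwich with vcovCL", {
  skip_if_not_installed("sandwich")
  df <- sim_rows(600, c(-1, 0.8, -0.5), seed = 11, rows_per_patient = 3)
  fit <- fit_cluster_logit(df, "y", c("x1", "x2"))
  g <- stats::glm(y ~ x1 + x2, binomial(), data = df)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  vc <- sandwich::vcovCL(g, cluster = df$patient_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$vcov), unname(vc), tolerance = 1e-3)
})

test_that("one observation per cluster reduces to the plain robust variance", {
  skip_if_not_installed("sandwich")
  df <- sim_rows(400, c(-0.5, 0.6), seed = 12)
  fit <- fit_cluster_logit(df, "y", "x1")
  g <- stats::glm(y ~ x1, binomial(), data = df)
  hc0 <- sandwich::vcovHC(g, type = "HC0")
  expect_equal(unname(fit$vcov), unname(hc0), tolerance = 1e-5)
})

test_that("clustered and naive variances agree for independent rows", {
  df <- sim_rows(4000, c(-1, 0.5), seed = 13, rows_per_patient = 4)
  fit <- fit_cluster_logit(df, "y", "x1")
  g <- stats::glm(y ~ x1, binomial(), data = df)
  ratio <- sqrt(diag(fit$vcov)) / sqrt(diag(vcov(g)))
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("refitting on patient-permuted rows yields identical coefficients", {
  df <- sim_rows(500, c(-1, 0.7, 0.2), seed = 14, rows_per_patient = 5)
  fit1 <- fit_cluster_logit(df, "y", c("x1", "x2"))
  perm <- withr::with_seed(1, df[sample.int(nrow(df)), ])
  fit2 <- fit_cluster_logit(perm, "y", c("x1", "x2"))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("separation and collinearity are explicit errors", {
  df <- tibble::tibble(patient_id = sprintf("p%02d", 1:40),
                       x1 = c(rep(0, 20), rep(1, 20)),
                       y = c(rep(0L, 20), rep(1L, 20)))
  expect_error(fit_cluster_logit(df, "y", "x1"), "separation.*x1")

  df2 <- sim_rows(200, c(-1, 0.5), seed = 15)
  df2$x2 <- 2 * df2$x1
  expect_error(fit_cluster_logit(df2, "y", c("x1", "x2")), "collinear.*x2")
})

test_that("standardized fits report coefficients on the original scale", {
  df <- sim_rows(2000, c(-1, 0.4, -0.6), seed = 16, rows_per_patient = 2)
  df$x1 <- df$x1 * 50 + 100 # badly conditioned scale
  f0 <- fit_cluster_logit(df, "y", c("x1", "x2"))
  f1 <- fit_cluster_logit(df, "y", c("x1", "x2"), standardize = TRUE)
  expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-5)
  expect_equal(predict_risk(f1, df), predict_risk(f0, df), tolerance = 1e-6)
})

test_that("risk prediction is the inverse-logit of the linear predictor", {
  df <- sim_rows(300, c(-0.5, 0.3, -0.2, 0.8), seed = 17)
  fit <- fit_cluster_logit(df, "y", c("x1", "x2", "x3"))

  zero_row <- tibble::tibble(x1 = 0, x2 = 0, x3 = 0)
  expect_equal(predict_risk(fit, zero_row),
               plogis(fit$coefficients[["(Intercept)"]]))

  null_fit <- fit
  null_fit$coefficients[] <- 0
  expect_equal(predict_risk(null_fit, df[1:5, ]), rep(0.5, 5))

  # manual dot product on a hand-built row
  row <- tibble::tibble(x1 = 1.5, x2 = -2, x3 = 0.25)
  b <- fit$coefficients
  manual <- 1 / (1 + exp(-(b[[1]] + b[[2]] * 1.5 + b[[3]] * -2 + b[[4]] * 0.25)))
  expect_equal(predict_risk(fit, row), manual, tolerance = 1e-12)

  expect_error(predict_risk(fit, tibble::tibble(x1 = 1, x2 = 2)), "x3")
  row_na <- tibble::tibble(x1 = 1, x2 = NA_real_, x3 = 0)
  expect_error(predict_risk(fit, row_na), "x2")
})

test_that("Wald ranking is deterministic and finds the dominant covariate", {
  first_rank <- integer(100)
  null_small <- logical(100)
  for (r in 1:100) {
    df <- sim_rows(800, c(-1, 1.2, 0.15, 0), seed = 7000 + r,
                   rows_per_patient = 2)
    fit <- fit_cluster_logit(df, "y", c("x1", "x2", "x3"))
    rk <- rank_covariates(fit)
    first_rank[r] <- rk$term[1] == "x1"
    null_small[r] <- abs(fit$z[["x3"]]) < 3
  }
  expect_gte(sum(first_rank), 95)
  expect_gte(sum(null_small), 99)

  # alphabetical tie-break on exactly equal |z|
  fake <- structure(list(z = c("(Intercept)" = 1, b = 2, a = 2, c = -2),
                         vcov = diag(4)), class = "aki_fit")
  expect_equal(rank_covariates(fake)$term, c("a", "b", "c"))
})

test_that("two identical-effect covariates earn statistically equal z-scores", {
  diffs <- vapply(1:60, function(r) {
    df <- sim_rows(600, c(-1, 0.6, 0.6), seed = 7500 + r, rows_per_patient = 2)
    fit <- fit_cluster_logit(df, "y", c("x1", "x2"))
    abs(fit$z[["x1"]]) - abs(fit$z[["x2"]])
  }, 0)
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 0.25)
})

test_that("closed-form export round-trips to the predictor", {
  df <- sim_rows(400, c(-0.8, 0.5, -0.3), seed = 19)
  fit <- fit_cluster_logit(df, "y", c("x1", "x2"))
  eq <- export_closed_form(fit)
  b <- parse_closed_form(eq)
  expect_equal(length(b), length(fit$covariates) + 1L)
  eta <- b[["(Intercept)"]] + b[["x1"]] * df$x1[1:100] + b[["x2"]] * df$x2[1:100]
  expect_equal(plogis(eta), predict_risk(fit, df[1:100, ]), tolerance = 1e-9)
})

test_that("class/outcome wrapper tags and filters correctly", {
  cohort <- make_cohort(400, seed = 21)
  kept <- apply_exclusions(cohort$patients, cohort$measurements)$patients
  ev <- detect_aki_events(cohort$measurements)
  rows <- label_rows(build_rows(kept, cohort$measurements, cohort$exposures, ev),
                     ev, cohort$ground_truth$patients)
  fit <- fit_discrete_logit(rows, "demographic", "aki24")
  expect_s3_class(fit, "aki_fit")
  expect_equal(fit$class_tag, "demographic")
  expect_setequal(fit$covariates, covariates_for_class("demographic"))
  expect_equal(glance(fit)$n_events, sum(rows$label_aki_24h))
  td <- tidy(fit)
  expect_equal(td$statistic, td$estimate / td$std.error)
  expect_error(fit_discrete_logit(rows, "demographic", "bogus"), "outcome")
})
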