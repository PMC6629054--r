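# Discrete-time logistic hazard models with patient-clustered sandwich
# variance. The optimizer is iteratively reweighted least squares with a
# relative log-likelihood convergence tolerance of 1e-8 and a cap of 100
# iterations; separation and singular designs are hard errors, never
# silently penalized fits.

outcome_label_column <- function(outcome) {
  switch(outcome,
    aki24 = "label_aki_24h",
    sustained_aki24 = "label_sustained_aki_24h",
    rrt = "label_rrt_24h",
    death = "label_death_24h",
    rlang::abort(sprintf(
      "unknown outcome '%s'; expected aki24, sustained_aki24, rrt or death",
      outcome))
  )
}

#' Fit a patient-clustered logistic regression
#'
#' The workhorse behind [fit_discrete_logit()]: maximum-likelihood logistic
#' regression on row-level binary labels, with a cluster-robust sandwich
#' covariance in which score contributions are summed within each patient
#' before the outer product (no small-sample adjustment, so with one row per
#' cluster it coincides with the ordinary heteroskedasticity-robust
#' estimator). Row order never affects the fit.
#'
#' @param data A data frame of complete-case rows.
#' @param outcome Name of the 0/1 outcome column.
#' @param covariates Character vector of covariate columns (may be empty for
#'   an intercept-only model).
#' @param cluster Name of the cluster id column (default `"patient_id"`).
#' @param standardize If `TRUE`, continuous covariates are centred/scaled
#'   internally for numerical conditioning; coefficients and covariance are
#'   reported back on the original scale.
#' @param class_tag,outcome_tag Metadata tags stored on the fit.
#' @return An object of class `aki_fit`.
#' @export
fit_cluster_logit <- function(data, outcome, covariates,
                              cluster = "patient_id", standardize = FALSE,
                              class_tag = "custom", outcome_tag = outcome) {
  assert_columns(data, c(outcome, covariates, cluster), "model data")
  y <- data[[outcome]]
  if (any(is.na(y)) || !all(y %in% c(0, 1))) {
    rlang::abort(sprintf("outcome '%s' must be 0/1 with no missing values",
                         outcome))
  }
  if (sum(y) == 0 || sum(y) == length(y)) {
    rlang::abort("outcome must contain at least one event and one non-event")
  }
  has_na <- covariates[vapply(covariates, function(v) anyNA(data[[v]]), TRUE)]
  if (length(has_na)) {
    rlang::abort(paste0("missing covariate values (apply complete_case_filter",
                        " first): ", paste(has_na, collapse = ", ")))
  }

  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[covariates]))
  storage.mode(X) <- "double"

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    rlang::abort(paste0("singular design; collinear column(s): ",
                        paste(bad, collapse = ", ")))
  }

  # optional internal standardization of continuous (non-binary) covariates
  centre <- rep(0, ncol(X))
  scale_ <- rep(1, ncol(X))
  if (standardize && length(covariates)) {
    for (j in seq_along(covariates)) {
      xj <- X[, j + 1L]
      if (length(unique(xj)) > 2L) {
        centre[j + 1L] <- mean(xj)
        scale_[j + 1L] <- stats::sd(xj)
        X[, j + 1L] <- (xj - centre[j + 1L]) / scale_[j + 1L]
      }
    }
  }

  fit <- irls_logit(X, y)

  # map back to the original covariate scale: b_j = b'_j / s_j,
  # b_0 = b'_0 - sum_j b'_j m_j / s_j
  if (standardize && length(covariates)) {
    A <- diag(1 / scale_)
    A[1, ] <- -centre / scale_
    A[1, 1] <- 1
    fit$beta <- drop(A %*% fit$beta)
    trans <- A
  } else {
    trans <- diag(ncol(X))
  }

  # cluster-robust sandwich on the original scale
  mu <- drop(inv_logit(cbind(`(Intercept)` = 1,
                             as.matrix(data[covariates])) %*%
                         fit$beta))
  X0 <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))
  storage.mode(X0) <- "double"
  w <- mu * (1 - mu)
  bread <- solve(crossprod(X0 * sqrt(w)))
  scores <- X0 * (y - mu)
  cl_scores <- rowsum(scores, group = data[[cluster]], reorder = FALSE)
  meat <- crossprod(cl_scores)
  vcov <- bread %*% meat %*% bread
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(X0), colnames(X0))

  beta <- setNames(fit$beta, colnames(X0))
  se <- sqrt(diag(vcov))
  structure(list(
    coefficients = beta,
    vcov = vcov,
    z = beta / se,
    class_tag = class_tag,
    outcome_tag = outcome_tag,
    covariates = covariates,
    n_rows = nrow(data),
    n_patients = dplyr::n_distinct(data[[cluster]]),
    n_events = sum(y),
    loglik = fit$loglik,
    iterations = fit$iterations,
    converged = fit$converged,
    dropped_fraction = attr(data, "dropped_fraction") %||% NA_real_
  ), class = "aki_fit")
}

# IRLS for the logistic likelihood. Convergence: relative log-likelihood
# change < 1e-8; cap 100 iterations; divergent coefficients are reported as
# separation with the offending covariate named.
irls_logit <- function(X, y, tol = 1e-8, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  loglik <- function(mu) {
    sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  }
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    xtwx <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(xtwx, crossprod(X, y - mu)),
                     error = function(e) {
                       rlang::abort("weighted design became singular during IRLS")
                     })
    beta <- beta + drop(step)
    ll <- loglik(inv_logit(drop(X %*% beta)))
    if (any(abs(beta) > 30)) {
      worst <- colnames(X)[which.max(abs(beta))]
      rlang::abort(paste0(
        "apparent complete separation (diverging coefficient): ", worst),
        class = "akiward_separation_error")
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 0.1)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(beta = beta, loglik = ll, iterations = iter, converged = converged)
}

#' Fit a covariate-class model for one outcome
#'
#' Fits the discrete-time logistic hazard for a covariate class
#' ([model_classes()]) and an outcome tag, after complete-case filtering for
#' that class. Each row is one prediction instance; the label is "event
#' within the next 24 hours"; patients are the inference clusters.
#'
#' @param rows Labeled observation rows (from [label_rows()]).
#' @param class One of [model_classes()].
#' @param outcome One of `"aki24"`, `"sustained_aki24"`, `"rrt"`, `"death"`.
#' @inheritParams fit_cluster_logit
#' @return An `aki_fit`.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(sim_config(n_patients = 400, seed = 3))
#' kept <- apply_exclusions(cohort$patients, cohort$measurements)$patients
#' ev <- detect_aki_events(cohort$measurements)
#' rows <- build_rows(kept, cohort$measurements, cohort$exposures, ev)
#' rows <- label_rows(rows, ev, cohort$ground_truth$patients)
#' fit <- fit_discrete_logit(rows, "demographic", "aki24")
#' tidy(fit)
#' }
fit_discrete_logit <- function(rows, class, outcome = "aki24",
                               standardize = FALSE) {
  label_col <- outcome_label_column(outcome)
  rows_cc <- complete_case_filter(rows, class)
  fit_cluster_logit(rows_cc, label_col, covariates_for_class(class),
                    cluster = "patient_id", standardize = standardize,
                    class_tag = class, outcome_tag = outcome)
}

#' Predict event risk for observation rows
#'
#' Inverse-logit of the fitted linear predictor. Rows must be complete-case
#' for the model's covariates: a missing required covariate is an error,
#' never a silent imputation.
#'
#' @param fit An `aki_fit`.
#' @param rows A data frame containing the model's covariates.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(fit, rows) {
  stopifnot(inherits(fit, "aki_fit"))
  missing_cols <- setdiff(fit$covariates, names(rows))
  if (length(missing_cols)) {
    rlang::abort(paste0("rows lack required covariate(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  has_na <- fit$covariates[vapply(fit$covariates,
                                  function(v) anyNA(rows[[v]]), TRUE)]
  if (length(has_na)) {
    rlang::abort(paste0("missing values in required covariate(s): ",
                        paste(has_na, collapse = ", ")))
  }
  X <- cbind(1, as.matrix(rows[fit$covariates]))
  storage.mode(X) <- "double"
  drop(inv_logit(X %*% fit$coefficients))
}

#' Rank covariates by Wald z-score magnitude
#'
#' Covariate importance in the multivariable model, measured as the absolute
#' Wald z-score (coefficient over cluster-robust standard error), in
#' descending order with alphabetical tie-break.
#'
#' @param fit An `aki_fit`.
#' @return Tibble `term`, `z`, `abs_z`, sorted.
#' @export
rank_covariates <- function(fit) {
  stopifnot(inherits(fit, "aki_fit"))
  keep <- names(fit$z) != "(Intercept)"
  tibble::tibble(term = names(fit$z)[keep], z = unname(fit$z[keep])) %>%
    dplyr::mutate(abs_z = abs(.data$z)) %>%
    dplyr::arrange(dplyr::desc(.data$abs_z), .data$term)
}

#' Export a fitted model as a closed-form equation
#'
#' Renders the linear predictor as a human-readable equation with named
#' covariates and full-precision coefficients, suitable for transcription
#' into an EHR rule engine. [parse_closed_form()] inverts it exactly.
#'
#' @param fit An `aki_fit`.
#' @return A single string, `"logit(p) = <intercept> + <b>*<name> + ..."`.
#' @export
export_closed_form <- function(fit) {
  stopifnot(inherits(fit, "aki_fit"))
  b <- fit$coefficients
  fmt <- function(x) sprintf("%.17g", x)
  terms <- c(fmt(b[[1]]),
             if (length(b) > 1L) paste0(fmt(b[-1]), "*", names(b)[-1]))
  paste0("logit(p) = ", paste(terms, collapse = " + "))
}

#' Parse a closed-form equation back into coefficients
#'
#' @param text A string produced by [export_closed_form()].
#' @return Named numeric coefficient vector (intercept first).
#' @export
parse_closed_form <- function(text) {
  rhs <- sub("^\\s*logit\\(p\\)\\s*=\\s*", "", text)
  parts <- strsplit(rhs, " + ", fixed = TRUE)[[1]]
  coefs <- numeric(length(parts))
  nms <- character(length(parts))
  for (i in seq_along(parts)) {
    bits <- strsplit(parts[i], "*", fixed = TRUE)[[1]]
    coefs[i] <- as.numeric(bits[1])
    nms[i] <- if (length(bits) > 1L) bits[2] else "(Intercept)"
  }
  setNames(coefs, nms)
}

#' @export
print.aki_fit <- function(x, ...) {
  cat(sprintf(
    "<aki_fit> class=%s outcome=%s | %d rows, %d patients, %d events | logLik %.2f (%d IRLS iterations%s)\n",
    x$class_tag, x$outcome_tag, x$n_rows, x$n_patients, x$n_events,
    x$loglik, x$iterations, if (x$converged) "" else ", NOT converged"))
  print(tidy(x), n = 10)
  invisible(x)
}

#' Tidy a fitted AKI hazard model
#'
#' @param x An `aki_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log-odds), `std.error`
#'   (cluster-robust), `statistic` (Wald z) and `p.value`.
#' @export
tidy.aki_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / se)))
  )
}

#' One-row model summary
#'
#' @param x An `aki_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit metadata.
#' @export
glance.aki_fit <- function(x, ...) {
  tibble::tibble(
    class = x$class_tag, outcome = x$outcome_tag,
    n_rows = x$n_rows, n_patients = x$n_patients, n_events = x$n_events,
    logLik = x$loglik, iterations = x$iterations, converged = x$converged,
    dropped_fraction = x$dropped_fraction
  )
}

#' Covariate-importance plot (Wald z magnitudes)
#'
#' @param object An `aki_fit`.
#' @param ... Unused.
#' @return A ggplot: covariates ordered by absolute Wald z-score.
#' @export
autoplot.aki_fit <- function(object, ...) {
  rk <- rank_covariates(object)
  ggplot2::ggplot(rk, ggplot2::aes(
    x = .data$abs_z,
    y = stats::reorder(.data$term, .data$abs_z))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|Wald z| (cluster-robust)", y = NULL,
                  title = sprintf("Covariate importance: %s model, %s",
                                  object$class_tag, object$outcome_tag)) +
    ggplot2::theme_minimal()
}
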