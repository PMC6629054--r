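# Cluster-aware discrimination evaluation: midrank AUC, patient-bootstrap
# confidence intervals, ROC operating points and PPV planning.

#' Area under the ROC curve (midrank / Mann-Whitney)
#'
#' The probability that a randomly chosen positive row outscores a randomly
#' chosen negative row, with ties counted half — the Mann-Whitney statistic
#' computed from midranks, which equals the trapezoidal area under the ROC
#' curve over all unique score thresholds.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (at least one of each class).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    rlang::abort("scores and labels must have equal length")
  }
  if (any(is.na(scores)) || any(!labels %in% c(0, 1))) {
    rlang::abort("scores must be non-missing and labels 0/1")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("labels must contain at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC points over all unique thresholds
#'
#' @inheritParams auc
#' @return Tibble `threshold`, `sensitivity`, `specificity`, one row per
#'   unique score (classification rule: positive iff score >= threshold),
#'   plus the degenerate all-negative rule; a monotone staircase from (0,0)
#'   to (1,1) in (1 - specificity, sensitivity) space.
#' @export
roc_points <- function(scores, labels) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    rlang::abort("labels must contain at least one positive and one negative")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # last row of each tied-score block gives the confusion counts for the
  # rule "positive iff score >= threshold"
  block_end <- cumsum(rle(s)$lengths)
  tibble::tibble(
    threshold = c(Inf, s[block_end]),
    sensitivity = c(0, cumsum(l == 1)[block_end] / n1),
    specificity = c(1, 1 - cumsum(l == 0)[block_end] / n0)
  )
}

#' Clustered AUC with a patient-bootstrap confidence interval
#'
#' Point estimate from [auc()]; interval from a percentile bootstrap that
#' resamples patients with replacement, moving all of a patient's rows
#' together, so the interval remains honest under within-patient dependence.
#' Resamples containing a single label class are redrawn and counted; if
#' more than half of all draws are degenerate the data are deemed too sparse
#' and an error is raised.
#'
#' @inheritParams auc
#' @param patient_ids Cluster id per row.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed (the interval is deterministic given the seed).
#' @param conf_level Confidence level (default 0.95).
#' @param stratum,class_tag,outcome_tag Optional metadata labels.
#' @return An object of class `aki_eval`.
#' @export
clustered_auc_ci <- function(scores, labels, patient_ids, B = 2000L,
                             seed = 1L, conf_level = 0.95, stratum = NA_character_,
                             class_tag = NA_character_,
                             outcome_tag = NA_character_) {
  if (B < 100) rlang::abort("B must be at least 100 bootstrap replicates")
  point <- auc(scores, labels)

  idx_by_pat <- split(seq_along(scores), patient_ids)
  pats <- names(idx_by_pat)
  n_pat <- length(pats)

  # exact probability that a patient resample misses every positive-carrying
  # (or every negative-carrying) patient, i.e. is single-class; when at least
  # half of resamples would be degenerate the data are too sparse to bootstrap
  k_pos <- sum(vapply(idx_by_pat, function(i) any(labels[i] == 1), TRUE))
  k_neg <- sum(vapply(idx_by_pat, function(i) any(labels[i] == 0), TRUE))
  p_degen <- ((n_pat - k_pos) / n_pat)^n_pat + ((n_pat - k_neg) / n_pat)^n_pat
  if (p_degen >= 0.5) {
    rlang::abort(paste0("degenerate data: at least half of patient resamples",
                        " would contain a single label class"))
  }

  boot <- numeric(B)
  n_redraws <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        take <- sample.int(n_pat, n_pat, replace = TRUE)
        idx <- unlist(idx_by_pat[take], use.names = FALSE)
        lb <- labels[idx]
        if (any(lb == 1) && any(lb == 0)) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 10L * B) { # safety valve; cannot trigger unless the
          rlang::abort("degenerate data: bootstrap redraw limit exceeded")
        }                          # degeneracy check above was borderline
      }
      boot[b] <- auc(scores[idx], lb)
    }
  })

  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(
    auc = point, ci_low = ci[1], ci_high = ci[2],
    conf_level = conf_level, B = B, n_redraws = n_redraws,
    n_rows = length(scores), n_patients = n_pat, n_events = sum(labels == 1),
    stratum = stratum, class_tag = class_tag, outcome_tag = outcome_tag,
    roc = roc_points(scores, labels)
  ), class = "aki_eval")
}

#' @export
print.aki_eval <- function(x, ...) {
  cat(sprintf(
    "<aki_eval> %s/%s%s: AUC %.2f (%.0f%% CI %.2f-%.2f); %d rows, %d patients, %d events\n",
    x$class_tag, x$outcome_tag,
    if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]"),
    x$auc, 100 * x$conf_level, x$ci_low, x$ci_high,
    x$n_rows, x$n_patients, x$n_events))
  invisible(x)
}

#' Tidy an evaluation result
#' @param x An `aki_eval`.
#' @param ... Unused.
#' @return One-row tibble of the AUC, CI and counts.
#' @export
tidy.aki_eval <- function(x, ...) {
  tibble::tibble(
    class = x$class_tag, outcome = x$outcome_tag, stratum = x$stratum,
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    n_rows = x$n_rows, n_patients = x$n_patients, n_events = x$n_events
  )
}

#' Class-by-outcome-by-stratum evaluation grid
#'
#' Scores every fitted model on every evaluation stratum and reports the
#' clustered AUC with its patient-bootstrap interval — the familiar grid of
#' covariate-class columns against outcome rows, with one block per
#' validation stratum.
#'
#' @param fits A list of `aki_fit` objects.
#' @param rows Labeled observation rows including a `partition` column (see
#'   [split_cohort()]).
#' @param strata Which partitions to evaluate (default: all except
#'   `"train"`).
#' @param B,seed Bootstrap replicates and seed passed to
#'   [clustered_auc_ci()].
#' @return A tibble with one row per (class, outcome, stratum): the AUC,
#'   CI bounds, counts, and a `roc` list-column of ROC points.
#' @export
evaluation_grid <- function(fits, rows, strata = NULL, B = 2000L, seed = 1L) {
  assert_columns(rows, "partition", "observation rows")
  if (is.null(strata)) strata <- setdiff(unique(rows$partition), "train")
  if (!length(fits)) rlang::abort("no fitted models supplied")

  combos <- tidyr::expand_grid(fit = fits, stratum = strata)
  out <- purrr::pmap(combos, function(fit, stratum) {
    if (!inherits(fit, "aki_fit")) {
      rlang::abort("fits must be a list of aki_fit objects")
    }
    sub <- rows[rows$partition == stratum, , drop = FALSE]
    sub <- complete_case_filter(sub, fit$class_tag)
    label_col <- outcome_label_column(fit$outcome_tag)
    if (!nrow(sub) || sum(sub[[label_col]]) == 0 ||
        sum(sub[[label_col]]) == nrow(sub)) {
      rlang::abort(sprintf(
        "cannot evaluate cell (class=%s, outcome=%s, stratum=%s): single-class labels",
        fit$class_tag, fit$outcome_tag, stratum))
    }
    ev <- clustered_auc_ci(predict_risk(fit, sub), sub[[label_col]],
                           sub$patient_id, B = B, seed = seed,
                           stratum = stratum, class_tag = fit$class_tag,
                           outcome_tag = fit$outcome_tag)
    dplyr::mutate(tidy(ev), roc = list(ev$roc))
  })
  dplyr::bind_rows(out)
}

#' Positive predictive value at an operating point
#'
#' Bayes' rule for a binary test:
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`.
#'
#' @param sensitivity,specificity,prevalence Values in (0, 1].
#' @return One-row tibble: `ppv` (full precision) and `ppv_percent`
#'   (rounded to the nearest whole percent).
#' @export
#' @examples
#' ppv_at_operating_point(0.80, 0.50, 0.15) # ~0.22, i.e. 22%
ppv_at_operating_point <- function(sensitivity, specificity, prevalence) {
  for (arg in c("sensitivity", "specificity", "prevalence")) {
    v <- get(arg)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v > 1) {
      rlang::abort(sprintf("%s must be a single value in (0, 1]", arg))
    }
  }
  ppv <- (sensitivity * prevalence) /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  tibble::tibble(ppv = ppv, ppv_percent = round(100 * ppv))
}

#' Choose a threshold achieving a target sensitivity or specificity
#'
#' Returns the ROC point whose achieved value of the constrained quantity is
#' closest to the target from the feasible side (sensitivity at or above a
#' sensitivity target; specificity at or above a specificity target), with
#' deterministic tie-break toward higher specificity.
#'
#' @param roc ROC points from [roc_points()].
#' @param sensitivity,specificity Exactly one target must be given.
#' @return One-row tibble `threshold`, `sensitivity`, `specificity`.
#' @export
operating_point <- function(roc, sensitivity = NULL, specificity = NULL) {
  if (!nrow(roc)) rlang::abort("empty ROC")
  if (is.null(sensitivity) == is.null(specificity)) {
    rlang::abort("supply exactly one of sensitivity or specificity targets")
  }
  if (!is.null(sensitivity)) {
    feas <- roc[roc$sensitivity >= sensitivity, , drop = FALSE]
    if (!nrow(feas)) feas <- roc[which.max(roc$sensitivity), , drop = FALSE]
    feas <- feas[order(feas$sensitivity - sensitivity, -feas$specificity), ]
  } else {
    feas <- roc[roc$specificity >= specificity, , drop = FALSE]
    if (!nrow(feas)) feas <- roc[which.max(roc$specificity), , drop = FALSE]
    feas <- feas[order(feas$specificity - specificity, -feas$sensitivity), ]
  }
  tibble::as_tibble(feas[1, c("threshold", "sensitivity", "specificity")])
}

#' ROC curve plot for one evaluation
#'
#' @param object An `aki_eval`.
#' @param ... Unused.
#' @return A ggplot of the ROC staircase with the chance diagonal.
#' @export
autoplot.aki_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(color = "firebrick") +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s model, %s (AUC %.2f, %.0f%% CI %.2f-%.2f)",
                      object$class_tag, object$outcome_tag, object$auc,
                      100 * object$conf_level, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Panelled ROC curves for an evaluation grid
#'
#' One panel per outcome, one curve per covariate class — the standard
#' multi-model ROC figure.
#'
#' @param grid Result of [evaluation_grid()].
#' @param stratum Which stratum to plot (default: first in the grid).
#' @return A ggplot.
#' @export
plot_roc_curves <- function(grid, stratum = NULL) {
  if (is.null(stratum)) stratum <- grid$stratum[1]
  g <- grid[grid$stratum == stratum, , drop = FALSE]
  curves <- g %>%
    dplyr::mutate(roc = purrr::map(.data$roc, tibble::as_tibble)) %>%
    dplyr::select("class", "outcome", "roc") %>%
    tidyr::unnest("roc")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity,
                               color = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = "Model",
                  title = sprintf("ROC curves (%s)", stratum)) +
    ggplot2::theme_minimal()
}
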