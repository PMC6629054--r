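# internal helpers shared across modules

# float tolerance for creatinine threshold comparisons (mg/dL); avoids
# boundary flips at exactly 0.3 and exactly 1.5x baseline
CREAT_TOL <- 1e-9

inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  rlang::abort(sprintf("invalid configuration: field '%s' %s", field, msg),
               class = "akiward_config_error")
}

assert_scalar_number <- function(x, field, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (x < min || x > max) {
    stop_field(field, sprintf("must be in [%s, %s]", min, max))
  }
  invisible(x)
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be probability(ies) in [0, 1]")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# minimum of `values` whose `times` fall in the half-open window [t - width, t)
window_min <- function(times, values, t, width) {
  in_win <- times >= (t - width) & times < t
  if (!any(in_win)) return(NA_real_)
  min(values[in_win])
}
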