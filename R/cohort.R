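#' Apply the study's inclusion/exclusion rules
#'
#' Filters a patient table by the study's four sequential rules and reports
#' flow-diagram-style attrition counts. A patient is included iff: a
#' discharge time is recorded, at least two inpatient creatinine values were
#' measured during the admission, no end-stage kidney disease (ESKD) code is
#' present, and the admission creatinine — the chronologically first
#' inpatient creatinine — is below 4 mg/dL. A patient violating several
#' rules is attributed to the first violated rule in that order
#' (first-rule-wins), so the per-rule counts plus the included count sum to
#' the input count.
#'
#' @param patients Patient table with `patient_id`, `discharge_time`, and an
#'   `eskd` logical column.
#' @param measurements Long measurement table (`patient_id`, `time_hours`,
#'   `analyte`, `value`).
#' @return A list with `patients` (the filtered table) and `report`, a
#'   one-row tibble of counts: `n_input`, `missing_discharge`,
#'   `fewer_than_two_creatinines`, `eskd_code`, `admission_creatinine_ge_4`,
#'   `included`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 50, seed = 2))
#' apply_exclusions(cohort$patients, cohort$measurements)$report
apply_exclusions <- function(patients, measurements) {
  assert_columns(patients, c("patient_id", "discharge_time", "eskd"),
                 "patient table")
  assert_columns(measurements, c("patient_id", "time_hours", "analyte", "value"),
                 "measurement table")
  if (anyDuplicated(patients$patient_id)) {
    rlang::abort("duplicate patient ids in patient table")
  }
  creat <- measurements %>% dplyr::filter(.data$analyte == "creatinine")
  if (any(!is.finite(creat$value)) || any(creat$value <= 0)) {
    rlang::abort("creatinine values must be positive")
  }

  creat_summary <- creat %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::arrange(.data$time_hours, .by_group = TRUE) %>%
    dplyr::summarise(n_creat = dplyr::n(),
                     first_creat = dplyr::first(.data$value),
                     .groups = "drop")

  p <- patients %>%
    dplyr::left_join(creat_summary, by = "patient_id") %>%
    dplyr::mutate(
      n_creat = dplyr::coalesce(.data$n_creat, 0L),
      rule = dplyr::case_when(
        is.na(.data$discharge_time) ~ "missing_discharge",
        .data$n_creat < 2L ~ "fewer_than_two_creatinines",
        .data$eskd ~ "eskd_code",
        .data$first_creat >= 4 ~ "admission_creatinine_ge_4",
        TRUE ~ "included"
      )
    )

  report <- tibble::tibble(
    n_input = nrow(p),
    missing_discharge = sum(p$rule == "missing_discharge"),
    fewer_than_two_creatinines = sum(p$rule == "fewer_than_two_creatinines"),
    eskd_code = sum(p$rule == "eskd_code"),
    admission_creatinine_ge_4 = sum(p$rule == "admission_creatinine_ge_4"),
    included = sum(p$rule == "included")
  )

  kept <- patients[p$rule == "included", , drop = FALSE]
  list(patients = kept, report = report)
}
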