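#' Covariate specification for the AKI risk models
#'
#' Returns the canonical covariate dictionary used throughout the package:
#' every model covariate with its class (the Table-1-style grouping that
#' defines the candidate model families) and its temporal kind. The classes
#' partition the covariates: time-invariant demographics and comorbidities;
#' carried-forward laboratory values (including the derived baseline and
#' last creatinine); the 48-hour creatinine delta, modeled on its own because
#' of its outsized predictive strength; medications; and procedures.
#'
#' @return A tibble with columns `name`, `class`
#'   (`demographic`, `laboratory`, `delta_creatinine`, `medication`,
#'   `procedure`) and `kind` (`time_invariant`, `carried_forward_numeric`,
#'   `carried_forward_binary`, `derived`).
#' @export
#' @examples
#' covariate_spec()
covariate_spec <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      name = c("age", "sex_male", "race_black", "surgical", "chf",
               "hypertension", "diabetes", "liver_disease", "elixhauser"),
      class = "demographic",
      kind = "time_invariant"
    ),
    tibble::tibble(
      name = c("bicarbonate", "bun", "chloride", "hemoglobin", "potassium",
               "sodium", "wbc", "platelets"),
      class = "laboratory",
      kind = "carried_forward_numeric"
    ),
    tibble::tibble(
      name = c("baseline_creatinine", "last_creatinine"),
      class = "laboratory",
      kind = "derived"
    ),
    tibble::tibble(
      name = "delta_creatinine_48h",
      class = "delta_creatinine",
      kind = "derived"
    ),
    tibble::tibble(
      name = c("ace_arb", "antibiotic", "chemotherapy", "diuretic",
               "narcotic", "nsaid", "vasopressor", "ppi", "statin"),
      class = "medication",
      kind = "carried_forward_binary"
    ),
    tibble::tibble(
      name = c("bipap", "contrast", "ventilation", "icu", "cardiac_cath",
               "rbc_transfusion"),
      class = "procedure",
      kind = "carried_forward_binary"
    )
  )
}

#' Model classes available for fitting
#' @return Character vector of valid model-class tags.
#' @export
model_classes <- function() {
  c("full", "demographic", "laboratory", "delta_creatinine",
    "medications", "procedures")
}

#' Covariates required by a model class
#'
#' Maps a model-class tag to the covariate names entering that model. The
#' `full` class uses every covariate.
#'
#' @param class One of [model_classes()].
#' @return Character vector of covariate names.
#' @export
covariates_for_class <- function(class) {
  spec <- covariate_spec()
  switch(class,
    full = spec$name,
    demographic = spec$name[spec$class == "demographic"],
    laboratory = spec$name[spec$class == "laboratory"],
    delta_creatinine = spec$name[spec$class == "delta_creatinine"],
    medications = spec$name[spec$class == "medication"],
    procedures = spec$name[spec$class == "procedure"],
    rlang::abort(sprintf(
      "unknown covariate class '%s'; expected one of: %s",
      class, paste(model_classes(), collapse = ", ")))
  )
}

# analyte names the generator and discretizer agree on
lab_analytes <- function() {
  c("creatinine", "bicarbonate", "bun", "chloride", "hemoglobin",
    "potassium", "sodium", "wbc", "platelets")
}

exposure_names <- function() {
  c("ace_arb", "antibiotic", "chemotherapy", "diuretic", "narcotic",
    "nsaid", "vasopressor", "ppi", "statin",
    "bipap", "contrast", "ventilation", "icu", "cardiac_cath",
    "rbc_transfusion")
}
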