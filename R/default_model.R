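#' The default risk-factor catalogue
#'
#' Returns the 31 variables of the cardiovascular risk network for
#' non-dialysis-dependent CKD: demographics, traditional cardiovascular
#' risk factors, and CKD-specific (non-traditional) factors. Continuous
#' variables carry conventional clinical cut-points: KDIGO G-stages for
#' eGFR, KDIGO-style A-categories for albuminuria/proteinuria (with the
#' urinary albumin-to-creatinine ratio available as an alternative
#' measurement channel on the same node), and widely used laboratory
#' thresholds elsewhere. Reference states are the lowest-risk clinical
#' category so that published effects, reported against a baseline group,
#' slot in per non-reference state.
#'
#' @return Named list of [variable_spec()] objects.
#' @export
calibra_variables <- function() {
  v <- list(
    variable_spec("age", "continuous", c("<50", "50-64", "65-79", "80+"),
                  cutpoints = c(50, 65, 80), units = "years",
                  reference_state = "65-79"),
    variable_spec("gender", "binary", c("female", "male"),
                  reference_state = "female"),
    variable_spec("hdl_cholesterol", "continuous", c("<40", "40-59", "60+"),
                  cutpoints = c(40, 60), units = "mg/dl",
                  reference_state = "40-59"),
    variable_spec("ldl_cholesterol", "continuous", c("<100", "100-159", "160+"),
                  cutpoints = c(100, 160), units = "mg/dl",
                  reference_state = "<100"),
    variable_spec("bmi", "continuous", c("<25", "25-29.9", "30-34.9", "35+"),
                  cutpoints = c(25, 30, 35), units = "kg/m2",
                  reference_state = "<25"),
    variable_spec("triglycerides", "continuous", c("<150", "150-199", "200+"),
                  cutpoints = c(150, 200), units = "mg/dl",
                  reference_state = "<150"),
    variable_spec("diabetes", "binary", c("no", "yes")),
    variable_spec("hypertension", "binary", c("no", "yes")),
    variable_spec("smoking", "categorical", c("never", "former", "current")),
    variable_spec("cerebrovascular_disease", "binary", c("no", "yes")),
    variable_spec("coronary_artery_disease", "binary", c("no", "yes")),
    variable_spec("congestive_heart_failure", "binary", c("no", "yes")),
    variable_spec("peripheral_vascular_disease", "binary", c("no", "yes")),
    variable_spec("atrial_fibrillation", "binary", c("no", "yes")),
    variable_spec("glucose", "continuous", c("<100", "100-125", "126+"),
                  cutpoints = c(100, 126), units = "mg/dl",
                  reference_state = "<100"),
    variable_spec("hstnt", "continuous", c("<14", "14+"),
                  cutpoints = 14, units = "ng/l", reference_state = "<14"),
    variable_spec("il6", "continuous", c("<5", "5+"),
                  cutpoints = 5, units = "ng/l", reference_state = "<5"),
    variable_spec("pth", "continuous", c("<65", "65-299", "300+"),
                  cutpoints = c(65, 300), units = "ng/l",
                  reference_state = "<65"),
    variable_spec("anemia", "binary", c("no", "yes")),
    variable_spec("alcohol", "categorical", c("none", "moderate", "heavy")),
    variable_spec("cancer", "binary", c("no", "yes")),
    variable_spec("copd", "binary", c("no", "yes")),
    variable_spec("connective_tissue_disorder", "binary", c("no", "yes")),
    variable_spec("liver_disease", "binary", c("no", "yes")),
    variable_spec("psychiatric_disease", "binary", c("no", "yes")),
    variable_spec("albumin", "continuous", c("<3.5", "3.5+"),
                  cutpoints = 3.5, units = "g/dl", reference_state = "3.5+"),
    variable_spec("proteinuria", "continuous", c("A1", "A2", "A3"),
                  cutpoints = c(0.15, 0.5), units = "g/24h",
                  reference_state = "A1",
                  alt_cutpoints = list(acr = c(3, 30))),
    variable_spec("crp", "continuous", c("<3", "3-9.9", "10+"),
                  cutpoints = c(3, 10), units = "mg/l",
                  reference_state = "<3"),
    variable_spec("egfr", "continuous", c("G5", "G4", "G3b", "G3a", "G2", "G1"),
                  cutpoints = c(15, 30, 45, 60, 90),
                  units = "ml/min/1.73m2", reference_state = "G1"),
    variable_spec("phosphate", "continuous", c("<4.5", "4.5+"),
                  cutpoints = 4.5, units = "mg/dl", reference_state = "<4.5"),
    variable_spec("uric_acid", "continuous", c("<7", "7+"),
                  cutpoints = 7, units = "mg/dl", reference_state = "<7")
  )
  stats::setNames(v, vapply(v, `[[`, character(1), "name"))
}

#' Build the example model from the shipped synthetic evidence
#'
#' Compiles the synthetic literature-evidence table and state prevalences
#' shipped with the package (`inst/extdata/synthetic_evidence.csv`,
#' `inst/extdata/synthetic_prevalences.json`) into the full 31-variable
#' network: studies are filtered for eligibility, pooled per variable/state
#' with sample-size weights, and inverted into conditional probability
#' tables. The effect sizes are synthetic — clinically plausible magnitudes
#' chosen to exercise the full pipeline, not pooled values from a
#' literature review — so the resulting model is a demonstration and test
#' model, not a clinically validated instrument.
#'
#' @param prior Outcome prior `P(Y=1)`, the assumed 1-year incidence of
#'   cardiovascular hospitalization (default 0.03, within the 2-4\% per
#'   year band typical of non-dialysis CKD cohorts).
#' @return A `calibra_model`.
#' @export
example_model <- function(prior = 0.03) {
  ev_path <- system.file("extdata", "synthetic_evidence.csv",
                         package = "calibra", mustWork = TRUE)
  pv_path <- system.file("extdata", "synthetic_prevalences.json",
                         package = "calibra", mustWork = TRUE)
  records <- filter_studies(read_evidence_csv(ev_path))
  prevalences <- jsonlite::fromJSON(pv_path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
  # group records by variable/state and pool
  keys <- vapply(records, function(r) paste(r$variable, r$exposure_state, sep = "\r"),
                 character(1))
  effects <- list()
  for (k in unique(keys)) {
    grp <- records[keys == k]
    pe <- pool_effect_sizes(grp)
    effects[[pe$variable]][[pe$exposure_state]] <- pe
  }
  build_network(
    prior = prior,
    variables = calibra_variables(),
    effects = effects,
    prevalences = prevalences,
    metadata = list(
      source = "synthetic evidence table shipped with the calibra package",
      note = "effect sizes are synthetic demonstration values"
    )
  )
}
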