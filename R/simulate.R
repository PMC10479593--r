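#' Configure cohort simulation
#'
#' @param n Cohort size.
#' @param seed Integer seed; a fixed seed makes the simulated table
#'   byte-identical across runs.
#' @param missingness Named per-variable missingness rates in `[0, 1]`
#'   (unnamed variables default to 0), or `NULL` to use the preset.
#' @param preset Missingness preset: `"none"`, `"registry-heavy"`
#'   (lipids, inflammatory markers and other purposefully prescribed labs
#'   40-70\% missing, as in routine-care registries), or
#'   `"protocol-light"` (a protocolized cohort study, at most 5\%
#'   missing). Ignored when `missingness` is given.
#' @param mechanism Missingness mechanism; only `"MCAR"` is supported.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n, seed = 1L,
                          missingness = NULL,
                          preset = c("none", "registry-heavy", "protocol-light"),
                          mechanism = "MCAR") {
  preset <- match.arg(preset)
  stopifnot(n >= 1, identical(mechanism, "MCAR"))
  if (!is.null(missingness)) {
    if (any(missingness < 0 | missingness > 1)) {
      stop("missingness rates must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         missingness = missingness, preset = preset, mechanism = mechanism),
    class = "cohort_config"
  )
}

# per-variable missingness rates for a preset and a variable name set
preset_rates <- function(preset, vnames) {
  rates <- stats::setNames(rep(0, length(vnames)), vnames)
  if (preset == "registry-heavy") {
    heavy <- c(hdl_cholesterol = 0.60, ldl_cholesterol = 0.60,
               triglycerides = 0.40, crp = 0.45, il6 = 0.70, hstnt = 0.70,
               uric_acid = 0.40, pth = 0.55, glucose = 0.30,
               proteinuria = 0.55, albumin = 0.20, smoking = 0.40,
               alcohol = 0.45, bmi = 0.10, phosphate = 0.15)
    light <- 0.05
    rates[] <- light
    rates[names(heavy)[names(heavy) %in% vnames]] <-
      heavy[names(heavy) %in% vnames]
    rates[intersect(c("age", "gender"), vnames)] <- 0
  } else if (preset == "protocol-light") {
    rates[] <- 0.03
    rates[intersect(c("age", "gender"), vnames)] <- 0
  }
  rates
}

#' Simulate a cohort from the generative model
#'
#' Reads the naive-Bayes network generatively: for each patient draw the
#' outcome `Y ~ Bernoulli(prior)`, then draw each variable's state from its
#' conditional probability column given `Y`. Missingness, if configured, is
#' applied afterwards by [apply_missingness()]. Reproducible: the same
#' model, `n` and seed give an identical table.
#'
#' @param model A `calibra_model`.
#' @param config A [cohort_config()] (or `n` may be given directly).
#' @return A data frame with one state-label column per model variable, an
#'   outcome column `cv_hosp_1y`, and a `row_id` column.
#' @export
simulate_cohort <- function(model, config) {
  if (is.numeric(config)) config <- cohort_config(n = config)
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  y <- stats::rbinom(n, 1, model$prior)
  out <- data.frame(row_id = seq_len(n))
  for (nm in names(model$variables)) {
    spec <- model$variables[[nm]]
    probs <- model$cpts[[nm]]$probs
    states <- character(n)
    for (yval in c(1L, 0L)) {
      idx <- y == yval
      if (any(idx)) {
        col <- if (yval == 1L) "p_event" else "p_noevent"
        states[idx] <- sample(spec$states, sum(idx), replace = TRUE,
                              prob = probs[, col])
      }
    }
    out[[nm]] <- states
  }
  out$cv_hosp_1y <- y
  rates <- config$missingness
  if (is.null(rates) && config$preset != "none") {
    rates <- preset_rates(config$preset, names(model$variables))
  }
  if (!is.null(rates) && any(rates > 0)) {
    out <- apply_missingness(out, rates)
  }
  out
}

#' Blank cells completely at random
#'
#' Applies MCAR missingness: each cell of each listed variable column is
#' set to `NA` independently with that variable's rate. The outcome and
#' `row_id` columns are never blanked. Draws come from the current RNG
#' state, so a seed set beforehand makes the result reproducible.
#'
#' @param table A cohort data frame.
#' @param rates Named numeric vector of per-variable rates in `[0, 1]`.
#' @return The table with cells blanked.
#' @export
apply_missingness <- function(table, rates) {
  if (any(rates < 0 | rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  protected <- c("cv_hosp_1y", "row_id")
  for (nm in names(rates)) {
    if (nm %in% protected || !nm %in% names(table) || rates[[nm]] == 0) next
    blank <- stats::runif(nrow(table)) < rates[[nm]]
    table[[nm]][blank] <- NA
  }
  table
}

#' The worked case-study patient
#'
#' A 45-year-old obese man (BMI 41) with stage G4 CKD (eGFR 25) most likely
#' caused by diabetes, a past smoker, with hypertension and COPD; blood
#' work: serum albumin 4.00 g/dl, calcium 8.9 mg/dl, hemoglobin 12.53 g/dl,
#' phosphate 4.19 mg/dl, PTH 289 ng/l, 24-hour proteinuria 2.49 g. All
#' other model variables — including C-reactive protein, resting hsTNT and
#' serum uric acid — are unmeasured.
#'
#' Raw measurements are mapped onto model states with the default
#' cut-points; hemoglobin enters the network through the anemia node
#' (12.53 g/dl in a man is below the 13 g/dl threshold), and serum calcium
#' has no corresponding node so it is carried in the raw record only.
#'
#' @return A list with `raw` (named list of the measurements as reported)
#'   and `evidence` (an [evidence_vector()] that validates against
#'   [calibra_variables()]).
#' @export
case_study_fixture <- function() {
  raw <- list(
    age = 45, gender = "male", bmi = 41, egfr = 25,
    etiology = "diabetes", smoking = "former",
    hypertension = "yes", copd = "yes",
    albumin = 4.00, calcium = 8.9, hemoglobin = 12.53,
    phosphate = 4.19, pth = 289, proteinuria = 2.49
  )
  vars <- calibra_variables()
  evidence <- evidence_vector(
    age = discretize(raw$age, vars$age),
    gender = "male",
    bmi = discretize(raw$bmi, vars$bmi),
    egfr = discretize(raw$egfr, vars$egfr),
    diabetes = "yes",
    smoking = "former",
    hypertension = "yes",
    copd = "yes",
    albumin = discretize(raw$albumin, vars$albumin),
    anemia = if (raw$hemoglobin < 13) "yes" else "no",
    phosphate = discretize(raw$phosphate, vars$phosphate),
    pth = discretize(raw$pth, vars$pth),
    proteinuria = discretize(raw$proteinuria, vars$proteinuria),
    .id = "case-study"
  )
  list(raw = raw, evidence = evidence)
}

#' Generate a small random model (testing utility)
#'
#' Draws a naive-Bayes model with random state counts and Dirichlet-like
#' conditional probability columns, used by the property-based test suites
#' and simulations. Uses the current RNG state.
#'
#' @param n_vars Number of variables.
#' @param max_states Maximum states per variable (at least 2).
#' @param prior_range Range the outcome prior is drawn from.
#' @return A `calibra_model`.
#' @export
random_model <- function(n_vars = 4, max_states = 3,
                         prior_range = c(0.02, 0.5)) {
  prior <- stats::runif(1, prior_range[1], prior_range[2])
  variables <- lapply(seq_len(n_vars), function(i) {
    k <- sample(2:max_states, 1)
    variable_spec(paste0("v", i), kind = if (k == 2) "binary" else "categorical",
                  states = paste0("s", seq_len(k)))
  })
  cpt_list <- lapply(variables, function(v) {
    k <- length(v$states)
    p1 <- stats::rgamma(k, 1) + 0.05
    p0 <- stats::rgamma(k, 1) + 0.05
    cbind(p_event = p1 / sum(p1), p_noevent = p0 / sum(p0))
  })
  names(cpt_list) <- vapply(variables, `[[`, character(1), "name")
  nb_model(prior, variables, cpt_list)
}
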