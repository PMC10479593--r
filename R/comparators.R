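#' Define an equation-based risk score
#'
#' Represents a published Cox-form cardiovascular risk equation (Framingham,
#' pooled-cohort ASCVD, INDANA and similar calculators) as data:
#' \deqn{risk = 1 - S_0^{\exp(LP)}, \qquad
#'       LP = \sum_j \beta_j (t_j(x_j) - c_j),}
#' where `t_j` is the input transform (identity or natural log), `c_j` a
#' centering constant and `S_0` the baseline survival at the score's horizon.
#' Coefficients may be stratified (typically by sex); the stratum variable's
#' value selects which coefficient set and baseline survival apply.
#'
#' @param name Score name.
#' @param required_inputs Character vector of input variable names (the
#'   stratum variable included).
#' @param coefficients Either a named numeric vector (unstratified) or a
#'   named list of named numeric vectors keyed by stratum value.
#' @param transforms Named character vector mapping inputs to `"identity"`
#'   or `"log"`; inputs not listed default to identity.
#' @param centers Named numeric vector of centering constants (same keying
#'   as `coefficients` entries when stratified); defaults to 0.
#' @param baseline_survival Either a single value in (0,1) or a named numeric
#'   vector keyed by stratum value.
#' @param stratum_var Name of the stratifying input (e.g. `"sex"`), or
#'   `NULL`.
#' @param lp_offset Constant subtracted from the linear predictor (published
#'   equations typically subtract the cohort-mean LP); a single value or a
#'   named vector keyed by stratum value. Default 0.
#' @param horizon_years Risk horizon of the published equation.
#' @return An object of class `equation_score`.
#' @export
equation_score <- function(name, required_inputs, coefficients,
                           transforms = NULL, centers = NULL,
                           baseline_survival, stratum_var = NULL,
                           lp_offset = 0, horizon_years = 10) {
  stopifnot(is.character(name), length(required_inputs) >= 1)
  if (any(baseline_survival <= 0) || any(baseline_survival >= 1)) {
    stop("baseline survival must lie in (0,1)", call. = FALSE)
  }
  stratified <- is.list(coefficients)
  coef_inputs <- if (stratified) {
    unique(unlist(lapply(coefficients, names)))
  } else {
    names(coefficients)
  }
  bad <- setdiff(coef_inputs, required_inputs)
  if (length(bad)) {
    stop("coefficients reference inputs not in required_inputs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(stratum_var) && !stratum_var %in% required_inputs) {
    stop("stratum_var must be listed in required_inputs", call. = FALSE)
  }
  structure(
    list(name = name, required_inputs = required_inputs,
         coefficients = coefficients, transforms = transforms,
         centers = centers, baseline_survival = baseline_survival,
         stratum_var = stratum_var, lp_offset = lp_offset,
         horizon_years = horizon_years),
    class = "equation_score"
  )
}

#' Load an equation score from JSON
#'
#' Reads a score specification in the dialect written by published-score
#' config files: top-level keys `name`, `required_inputs`, `transforms`,
#' `coefficients`, `centers`, `baseline_survival`, `stratum_var`,
#' `horizon_years`.
#'
#' @param path Path to a JSON file.
#' @return An `equation_score`.
#' @export
load_equation_score <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  for (field in c("name", "required_inputs", "coefficients", "baseline_survival")) {
    if (is.null(doc[[field]])) {
      stop("score file schema violation: missing field '", field, "'",
           call. = FALSE)
    }
  }
  to_named_num <- function(x) {
    if (is.null(x)) return(NULL)
    stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  coefs <- doc$coefficients
  if (is.list(coefs) && all(vapply(coefs, is.list, logical(1)))) {
    coefs <- lapply(coefs, to_named_num)
  } else {
    coefs <- to_named_num(coefs)
  }
  bs <- doc$baseline_survival
  bs <- if (is.list(bs)) to_named_num(bs) else as.numeric(bs)
  equation_score(
    name = doc$name,
    required_inputs = unlist(doc$required_inputs),
    coefficients = coefs,
    transforms = if (!is.null(doc$transforms)) unlist(doc$transforms),
    centers = if (is.list(doc$centers) && all(vapply(doc$centers, is.list, logical(1)))) {
      lapply(doc$centers, to_named_num)
    } else {
      to_named_num(doc$centers)
    },
    baseline_survival = bs,
    stratum_var = doc$stratum_var,
    lp_offset = if (is.null(doc$lp_offset)) 0 else {
      if (is.list(doc$lp_offset)) to_named_num(doc$lp_offset) else as.numeric(doc$lp_offset)
    },
    horizon_years = if (!is.null(doc$horizon_years)) doc$horizon_years else 10
  )
}

# fetch a possibly-stratified component for a stratum value
pick_stratum <- function(x, stratum) {
  if (is.list(x)) {
    if (is.null(stratum) || is.null(x[[stratum]])) {
      stop("no coefficient stratum for value '", stratum, "'", call. = FALSE)
    }
    x[[stratum]]
  } else {
    x
  }
}

#' Compute an equation score for one patient
#'
#' Evaluates the Cox-form risk if every required input is present and
#' finite; otherwise returns a not-computable result naming the missing
#' inputs. This is the complete-case behavior of equation-based scores:
#' unlike the naive-Bayes model, a single missing input makes the score
#' incalculable.
#'
#' @param spec An [equation_score()].
#' @param patient Named list or one-row data frame of input values.
#' @return An object of class `score_result` with fields `risk` (numeric or
#'   `NA`), `computable` (logical), `missing_inputs`, `lp`.
#' @export
compute_equation_score <- function(spec, patient) {
  patient <- as.list(patient)
  present <- vapply(spec$required_inputs, function(nm) {
    v <- patient[[nm]]
    !is.null(v) && !is.na(v) && (!is.character(v) || nzchar(trimws(v)))
  }, logical(1))
  if (!all(present)) {
    return(structure(
      list(risk = NA_real_, computable = FALSE,
           missing_inputs = spec$required_inputs[!present], lp = NA_real_),
      class = "score_result"))
  }
  stratum <- if (!is.null(spec$stratum_var)) {
    as.character(patient[[spec$stratum_var]])
  }
  beta <- pick_stratum(spec$coefficients, stratum)
  centers <- pick_stratum(spec$centers, stratum)
  s0 <- if (length(spec$baseline_survival) > 1L || !is.null(names(spec$baseline_survival))) {
    pick_stratum(as.list(spec$baseline_survival), stratum)
  } else {
    spec$baseline_survival
  }
  off <- spec$lp_offset
  if (is.null(off)) off <- 0
  if (!is.null(names(off)) || length(off) > 1L) {
    off <- pick_stratum(as.list(off), stratum)
  }
  lp <- -as.numeric(off)
  for (nm in names(beta)) {
    x <- as.numeric(patient[[nm]])
    tr <- if (!is.null(spec$transforms) && !is.na(spec$transforms[nm]) &&
              identical(unname(spec$transforms[nm]), "log")) log(x) else x
    ctr <- if (!is.null(centers) && !is.na(centers[nm])) centers[[nm]] else 0
    lp <- lp + beta[[nm]] * (tr - ctr)
  }
  if (!is.finite(lp)) {
    return(structure(
      list(risk = NA_real_, computable = FALSE,
           missing_inputs = character(0), lp = lp),
      class = "score_result"))
  }
  structure(
    list(risk = 1 - s0^exp(lp), computable = TRUE,
         missing_inputs = character(0), lp = lp),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("<score> risk = %.4f (LP = %.4f)\n", x$risk, x$lp))
  } else {
    cat("<score> not computable; missing:",
        paste(x$missing_inputs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Computability of an equation score over a cohort
#'
#' Reports the fraction of rows on which the score can be computed (all
#' required inputs present) and the per-variable missingness rates among
#' the required inputs — quantifying how far an equation-based score falls
#' short of full coverage in registry data.
#'
#' @param spec An [equation_score()].
#' @param cohort A data frame.
#' @return A list with `fraction_computable`, `n_computable`, `n_total` and
#'   a data frame `per_variable` (`variable`, `missing_rate`).
#' @export
computability_report <- function(spec, cohort) {
  stopifnot(is.data.frame(cohort))
  miss <- vapply(spec$required_inputs, function(nm) {
    if (!nm %in% names(cohort)) return(1)
    col <- cohort[[nm]]
    mean(is.na(col) | (is.character(col) & !nzchar(trimws(as.character(col)))))
  }, numeric(1))
  row_ok <- rep(TRUE, nrow(cohort))
  for (nm in spec$required_inputs) {
    if (!nm %in% names(cohort)) {
      row_ok[] <- FALSE
      break
    }
    col <- cohort[[nm]]
    row_ok <- row_ok & !(is.na(col) | (is.character(col) & !nzchar(trimws(as.character(col)))))
  }
  list(
    score = spec$name,
    fraction_computable = mean(row_ok),
    n_computable = sum(row_ok),
    n_total = nrow(cohort),
    per_variable = data.frame(variable = spec$required_inputs,
                              missing_rate = unname(miss), row.names = NULL)
  )
}

#' Score a cohort with an equation score
#'
#' Vector version of [compute_equation_score()]: returns the risk for
#' computable rows and `NA` elsewhere.
#'
#' @param spec An [equation_score()].
#' @param cohort A data frame.
#' @return Numeric vector of risks, `NA` where not computable.
#' @export
batch_equation_score <- function(spec, cohort) {
  vapply(seq_len(nrow(cohort)), function(i) {
    compute_equation_score(spec, cohort[i, , drop = FALSE])$risk
  }, numeric(1))
}
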