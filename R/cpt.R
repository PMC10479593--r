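#' Invert an odds ratio into conditional exposure probabilities
#'
#' Given an odds ratio for a binary exposure, the outcome prevalence
#' `P(Y=1)` and the marginal exposure prevalence `P(E=1)`, solves the 2x2
#' table exactly for `a = P(E=1|Y=1)` and `b = P(E=1|Y=0)` under the two
#' constraints
#' \deqn{P(E=1) = P(Y=1) a + (1 - P(Y=1)) b, \quad
#'       \frac{a/(1-a)}{b/(1-b)} = OR.}
#' Substituting the margin constraint yields a quadratic in `b`; the root
#' lying in (0,1) together with an admissible `a` is returned.
#'
#' @param or_value Odds ratio (positive).
#' @param outcome_prev Outcome prevalence `P(Y=1)` in (0,1).
#' @param exposure_prev Marginal exposure prevalence `P(E=1)` in (0,1).
#' @return Numeric vector `c(p_event, p_noevent)` = `(P(E=1|Y=1), P(E=1|Y=0))`.
#' @export
or_to_conditionals <- function(or_value, outcome_prev, exposure_prev) {
  stopifnot(or_value > 0, outcome_prev > 0, outcome_prev < 1,
            exposure_prev > 0, exposure_prev < 1)
  p <- outcome_prev; q <- exposure_prev; c1 <- 1 - p
  if (abs(or_value - 1) < 1e-14) {
    return(c(p_event = q, p_noevent = q))
  }
  # c1*(1-OR) b^2 - (c1 + q + OR*(p - q)) b + q = 0
  A <- c1 * (1 - or_value)
  B <- -(c1 + q + or_value * (p - q))
  C <- q
  disc <- B * B - 4 * A * C
  if (disc < 0) {
    stop("infeasible OR/prevalence combination: margin constraint P(E)=",
         q, " with OR=", or_value, " admits no real solution", call. = FALSE)
  }
  roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
  for (b in roots) {
    if (b > 0 && b < 1) {
      a <- (q - c1 * b) / p
      if (a > 0 && a < 1) {
        return(c(p_event = a, p_noevent = b))
      }
    }
  }
  stop("infeasible OR/prevalence combination: no root with both conditionals ",
       "in (0,1) for OR=", or_value, ", P(Y=1)=", p, ", P(E=1)=", q,
       call. = FALSE)
}

#' Invert a risk ratio into conditional exposure probabilities
#'
#' Given a risk ratio `RR = P(Y=1|E=1)/P(Y=1|E=0)`, the outcome prevalence
#' and the exposure prevalence, solves exactly for
#' `(P(E=1|Y=1), P(E=1|Y=0))` via Bayes inversion. Hazard ratios over the
#' one-year horizon are handled as risk ratios.
#'
#' @inheritParams or_to_conditionals
#' @param rr_value Risk ratio (positive).
#' @return Numeric vector `c(p_event, p_noevent)`.
#' @export
rr_to_conditionals <- function(rr_value, outcome_prev, exposure_prev) {
  stopifnot(rr_value > 0, outcome_prev > 0, outcome_prev < 1,
            exposure_prev > 0, exposure_prev < 1)
  p <- outcome_prev; q <- exposure_prev
  # RR = P(Y|E=1)/P(Y|E=0); with Bayes both risks reduce to
  # a (1-q) / ((1-a) q) = RR  =>  a = RR q / (1 - q + RR q)
  a <- rr_value * q / (1 - q + rr_value * q)
  b <- (q - p * a) / (1 - p)
  if (b <= 0 || b >= 1 || a <= 0 || a >= 1) {
    stop("infeasible RR/prevalence combination: RR=", rr_value,
         " with P(Y=1)=", p, ", P(E=1)=", q,
         " implies a conditional probability outside (0,1)", call. = FALSE)
  }
  c(p_event = a, p_noevent = b)
}

#' Convert a pooled effect into conditional probabilities
#'
#' Dispatches on the effect measure: odds ratios through
#' [or_to_conditionals()], risk and hazard ratios through
#' [rr_to_conditionals()] (HR approximated as RR over the 1-year horizon).
#'
#' @param measure `"OR"`, `"RR"` or `"HR"`.
#' @param value Effect size on the ratio scale.
#' @inheritParams or_to_conditionals
#' @return Numeric vector `c(p_event, p_noevent)`.
#' @export
effect_to_conditionals <- function(measure, value, outcome_prev, exposure_prev) {
  switch(measure,
         OR = or_to_conditionals(value, outcome_prev, exposure_prev),
         RR = ,
         HR = rr_to_conditionals(value, outcome_prev, exposure_prev),
         stop("unknown effect measure '", measure, "'", call. = FALSE))
}

# additive smoothing away from {0,1}, column renormalized
smooth_column <- function(p, eps = 1e-6) {
  p <- p + eps
  p / sum(p)
}

#' Build a conditional probability table for one variable
#'
#' Each non-reference state carries a pooled effect versus the reference
#' state and a marginal state prevalence. The effect is inverted state-wise
#' (the state collapsed against the rest) into `P(state|Y=1)` and
#' `P(state|Y=0)`; the reference state takes the residual mass and both
#' columns are smoothed away from the boundary and renormalized.
#'
#' @param spec A [variable_spec()].
#' @param effects Named list mapping each non-reference state to a
#'   [pool_effect_sizes()] result (or a list with fields `measure` and
#'   `pooled_effect`).
#' @param prevalences Named numeric vector of marginal state prevalences
#'   `P(X = s)` for every non-reference state (each in (0,1), summing to
#'   less than 1).
#' @param outcome_prev Outcome prevalence `P(Y=1)`.
#' @param eps Additive smoothing constant.
#' @return An object of class `conditional_table` with matrix `probs`
#'   (rows = states, columns `p_event`, `p_noevent`).
#' @export
conditional_table <- function(spec, effects, prevalences, outcome_prev,
                              eps = 1e-6) {
  stopifnot(inherits(spec, "calibra_variable"))
  non_ref <- setdiff(spec$states, spec$reference_state)
  for (s in non_ref) {
    if (is.null(effects[[s]])) {
      stop("incomplete knowledge for variable '", spec$name, "': state '", s,
           "' has no pooled effect", call. = FALSE)
    }
    if (is.na(prevalences[s])) {
      stop("incomplete knowledge for variable '", spec$name, "': state '", s,
           "' has no exposure prevalence", call. = FALSE)
    }
  }
  if (sum(prevalences[non_ref]) >= 1) {
    stop("variable '", spec$name, "': non-reference state prevalences sum to >= 1",
         call. = FALSE)
  }
  probs <- matrix(NA_real_, nrow = length(spec$states), ncol = 2,
                  dimnames = list(spec$states, c("p_event", "p_noevent")))
  for (s in non_ref) {
    eff <- effects[[s]]
    ab <- effect_to_conditionals(eff$measure, eff$pooled_effect,
                                 outcome_prev, prevalences[[s]])
    probs[s, ] <- ab
  }
  probs[spec$reference_state, ] <- pmax(
    1 - colSums(probs[non_ref, , drop = FALSE]), 0
  )
  probs[, 1] <- smooth_column(probs[, 1], eps)
  probs[, 2] <- smooth_column(probs[, 2], eps)
  structure(list(variable = spec$name, probs = probs),
            class = "conditional_table")
}

#' Assemble the naive-Bayes network
#'
#' Combines the outcome prior, variable definitions, pooled literature
#' effects and exposure prevalences into the full model: one conditional
#' probability table per variable, all variables children of the single
#' binary outcome node.
#'
#' @param prior Outcome prior `P(Y=1)` in (0,1).
#' @param variables List of [variable_spec()] objects.
#' @param effects Nested named list: `effects[[variable]][[state]]` is a
#'   pooled effect for that non-reference state.
#' @param prevalences Nested named list/vector:
#'   `prevalences[[variable]][[state]]` is the marginal prevalence of that
#'   state.
#' @param metadata Optional named list of provenance strings.
#' @param eps Additive smoothing constant for CPT cells.
#' @return An object of class `calibra_model`.
#' @export
build_network <- function(prior, variables, effects, prevalences,
                          metadata = list(), eps = 1e-6) {
  stopifnot(prior > 0, prior < 1, length(variables) >= 1)
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  cpts <- lapply(variables, function(spec) {
    pv <- prevalences[[spec$name]]
    conditional_table(
      spec,
      effects = effects[[spec$name]],
      prevalences = stats::setNames(as.numeric(pv), names(pv)),
      outcome_prev = prior, eps = eps
    )
  })
  model <- structure(
    list(prior = prior, variables = variables, cpts = cpts,
         metadata = metadata),
    class = "calibra_model"
  )
  validate_model(model)
  model
}

#' Construct a model directly from conditional probability tables
#'
#' Low-level constructor used for toy models, tests and deserialization,
#' bypassing effect-size inversion. Probabilities are validated, not
#' re-smoothed.
#'
#' @param prior Outcome prior in (0,1).
#' @param variables List of [variable_spec()] objects.
#' @param cpt_list Named list: for each variable a matrix with one row per
#'   state and columns `p_event`, `p_noevent`, each column summing to 1.
#' @param metadata Optional named list.
#' @return A `calibra_model`.
#' @export
nb_model <- function(prior, variables, cpt_list, metadata = list()) {
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  cpts <- lapply(names(variables), function(nm) {
    m <- as.matrix(cpt_list[[nm]])
    colnames(m) <- c("p_event", "p_noevent")
    rownames(m) <- variables[[nm]]$states
    structure(list(variable = nm, probs = m), class = "conditional_table")
  })
  names(cpts) <- names(variables)
  model <- structure(
    list(prior = prior, variables = variables, cpts = cpts, metadata = metadata),
    class = "calibra_model"
  )
  validate_model(model)
  model
}

#' Validate a model's structural invariants
#'
#' Checks the outcome prior lies in (0,1), that there is exactly one CPT per
#' variable with rows matching the variable's states, that every CPT column
#' sums to 1 within 1e-9 and every cell lies strictly inside (0,1).
#'
#' @param model A `calibra_model`.
#' @return The model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  if (!is.numeric(model$prior) || model$prior <= 0 || model$prior >= 1) {
    stop("model validation: prior must lie in (0,1)", call. = FALSE)
  }
  vnames <- vapply(model$variables, `[[`, character(1), "name")
  if (!setequal(vnames, names(model$cpts)) ||
      length(model$cpts) != length(vnames)) {
    stop("model validation: exactly one CPT per variable is required; variables (",
         paste(vnames, collapse = ", "), ") vs CPTs (",
         paste(names(model$cpts), collapse = ", "), ")", call. = FALSE)
  }
  for (nm in vnames) {
    spec <- model$variables[[nm]]
    probs <- model$cpts[[nm]]$probs
    if (!identical(rownames(probs), spec$states)) {
      stop("model validation: CPT rows for '", nm,
           "' do not match the variable's states", call. = FALSE)
    }
    sums <- colSums(probs)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("model validation: CPT columns for '", nm, "' sum to (",
           paste(signif(sums, 10), collapse = ", "), "), expected 1", call. = FALSE)
    }
    if (any(probs <= 0) || any(probs >= 1)) {
      stop("model validation: CPT for '", nm,
           "' has cells at or outside (0,1); apply smoothing", call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.calibra_model <- function(x, ...) {
  cat(sprintf("<naive-Bayes risk model> prior P(Y=1) = %.4g, %d variables\n",
              x$prior, length(x$variables)))
  cat("  ", paste(names(x$variables), collapse = ", "), "\n", sep = "")
  invisible(x)
}
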