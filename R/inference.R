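#' Create an evidence vector
#'
#' A patient's observed variable states. Variables not mentioned are treated
#' as missing and are marginalized exactly during inference; there is no
#' distinction between "not measured" and "not recorded".
#'
#' @param ... Named state assignments, e.g. `diabetes = "yes"`, or a single
#'   named list/character vector.
#' @param .id Optional source record identifier.
#' @return An object of class `evidence_vector`.
#' @export
evidence_vector <- function(..., .id = NULL) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args))) {
    args <- as.list(args[[1]])
  }
  if (length(args) && (is.null(names(args)) || any(!nzchar(names(args))))) {
    stop("evidence assignments must all be named", call. = FALSE)
  }
  if (anyDuplicated(names(args))) {
    stop("duplicate variables in evidence: ",
         paste(unique(names(args)[duplicated(names(args))]), collapse = ", "),
         call. = FALSE)
  }
  assignments <- vapply(args, as.character, character(1))
  structure(list(assignments = assignments, source_record_id = .id),
            class = "evidence_vector")
}

#' @export
print.evidence_vector <- function(x, ...) {
  cat(sprintf("<evidence> %d observed variable(s)\n", length(x$assignments)))
  if (length(x$assignments)) {
    cat(paste0("  ", names(x$assignments), " = ", x$assignments, collapse = "\n"),
        "\n")
  }
  invisible(x)
}

# check evidence against model variable specs; returns named character vector
validate_evidence <- function(model, evidence) {
  if (inherits(evidence, "evidence_vector")) {
    asg <- evidence$assignments
  } else {
    asg <- vapply(as.list(evidence), as.character, character(1))
  }
  for (nm in names(asg)) {
    spec <- model$variables[[nm]]
    if (is.null(spec)) {
      stop("evidence validation: unknown variable '", nm, "'", call. = FALSE)
    }
    if (!asg[[nm]] %in% spec$states) {
      stop("evidence validation: '", asg[[nm]], "' is not a state of variable '",
           nm, "' (states: ", paste(spec$states, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  asg
}

#' Log likelihood ratio of an observed state
#'
#' Returns `log(P(state | Y=1) / P(state | Y=0))` from the smoothed
#' conditional probability table — the additive contribution of one observed
#' item to the posterior log odds. Always finite for a valid (smoothed)
#' model.
#'
#' @param model A `calibra_model`.
#' @param variable Variable name.
#' @param state State label.
#' @return A single numeric value (natural log).
#' @export
log_likelihood_ratio <- function(model, variable, state) {
  asg <- stats::setNames(state, variable)
  validate_evidence(model, asg)
  probs <- model$cpts[[variable]]$probs
  log(probs[state, "p_event"]) - log(probs[state, "p_noevent"])
}

#' Posterior risk for one patient
#'
#' Computes `P(Y=1 | evidence)` under the naive-Bayes model in log space:
#' posterior log odds = prior log odds + the sum of per-item log likelihood
#' ratios over the observed variables. Unobserved variables contribute
#' nothing — under the naive-Bayes factorization this is the exact
#' marginalization over all their states, so no imputation is ever needed.
#'
#' @param model A `calibra_model`.
#' @param evidence An [evidence_vector()], named list, or named character
#'   vector of state assignments; may be empty (posterior = prior).
#' @return An object of class `risk_result` with fields `posterior`,
#'   `prior_used`, `log_odds`, `contributions` (named, natural log),
#'   `n_observed`, `n_missing`.
#' @export
predict_risk <- function(model, evidence = evidence_vector()) {
  if (length(model$variables) == 0L) {
    stop("cannot score with an empty model", call. = FALSE)
  }
  asg <- validate_evidence(model, evidence)
  contributions <- vapply(names(asg), function(nm) {
    probs <- model$cpts[[nm]]$probs
    log(probs[asg[[nm]], "p_event"]) - log(probs[asg[[nm]], "p_noevent"])
  }, numeric(1))
  log_odds <- stats::qlogis(model$prior) + sum(contributions)
  structure(
    list(posterior = stats::plogis(log_odds),
         prior_used = model$prior,
         log_odds = log_odds,
         contributions = contributions,
         n_observed = length(asg),
         n_missing = length(model$variables) - length(asg)),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk> P(Y=1 | evidence) = %.4f (prior %.4f; %d observed, %d missing)\n",
              x$posterior, x$prior_used, x$n_observed, x$n_missing))
  invisible(x)
}

#' Score a cohort table
#'
#' Applies the model to every row of a patient table. Columns are matched to
#' model variables by name; unmappable columns are ignored with a warning.
#' Blank or `NA` cells are missing. Raw numeric values in columns of
#' continuous variables are discretized with the variable's cut-points;
#' state labels are used as-is. Rows with no observed variable are scored at
#' the prior. Output order follows input order and scoring is deterministic.
#'
#' @param model A `calibra_model`.
#' @param cohort A data frame, one row per patient.
#' @param outcome_col Name of an outcome column to carry through (ignored for
#'   scoring); default `"cv_hosp_1y"`.
#' @return A data frame with columns `posterior`, `log_odds`, `n_observed`,
#'   `n_missing` (plus the outcome column when present), one row per input
#'   row.
#' @export
batch_score <- function(model, cohort, outcome_col = "cv_hosp_1y") {
  stopifnot(is.data.frame(cohort))
  vnames <- names(model$variables)
  cols <- setdiff(names(cohort), outcome_col)
  unknown <- setdiff(cols, vnames)
  if (length(unknown)) {
    warning("ignoring columns not in the model: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  usable <- intersect(cols, vnames)
  n <- nrow(cohort)
  total_llr <- numeric(n)
  n_obs <- integer(n)
  for (nm in usable) {
    spec <- model$variables[[nm]]
    col <- cohort[[nm]]
    states <- rep(NA_character_, n)
    if (is.numeric(col) && spec$kind == "continuous") {
      states <- discretize(col, spec)
    } else {
      chr <- as.character(col)
      chr[!is.na(chr) & !nzchar(trimws(chr))] <- NA_character_
      if (spec$kind == "continuous") {
        # state labels pass through; numeric strings are discretized
        is_state <- chr %in% spec$states
        num <- suppressWarnings(as.numeric(chr))
        states[is_state] <- chr[is_state]
        conv <- !is_state & !is.na(num)
        states[conv] <- discretize(num[conv], spec)
        bad <- !is.na(chr) & !is_state & is.na(num)
      } else {
        states <- chr
        bad <- !is.na(chr) & !chr %in% spec$states
      }
      if (any(bad)) {
        stop("batch_score: column '", nm, "' contains values that are neither ",
             "states nor interpretable measurements: ",
             paste(utils::head(unique(chr[bad]), 3), collapse = ", "),
             call. = FALSE)
      }
    }
    probs <- model$cpts[[nm]]$probs
    llr_by_state <- log(probs[, "p_event"]) - log(probs[, "p_noevent"])
    idx <- match(states, spec$states)
    obs <- !is.na(idx)
    total_llr[obs] <- total_llr[obs] + llr_by_state[idx[obs]]
    n_obs <- n_obs + as.integer(obs)
  }
  log_odds <- stats::qlogis(model$prior) + total_llr
  out <- data.frame(
    posterior = stats::plogis(log_odds),
    log_odds = log_odds,
    n_observed = n_obs,
    n_missing = length(vnames) - n_obs
  )
  if (outcome_col %in% names(cohort)) out[[outcome_col]] <- cohort[[outcome_col]]
  out
}

#' Brute-force posterior by full joint enumeration
#'
#' Test oracle: materializes the full joint distribution over the outcome
#' and every model variable, conditions on the evidence by summing the joint
#' over all states of unobserved variables, and returns the exact
#' `P(Y=1 | evidence)`. Only feasible for small models (product of state
#' counts at most 1e6).
#'
#' @param model A `calibra_model`.
#' @param evidence Evidence as in [predict_risk()].
#' @return Posterior probability (single numeric).
#' @export
enumerate_joint_posterior <- function(model, evidence = evidence_vector()) {
  asg <- validate_evidence(model, evidence)
  sizes <- vapply(model$variables, function(v) length(v$states), integer(1))
  if (prod(sizes) > 1e6) {
    stop("state space too large to enumerate (", prod(sizes),
         " > 1e6 configurations)", call. = FALSE)
  }
  grids <- lapply(model$variables, function(v) v$states)
  grids$.Y <- c("1", "0")
  joint <- expand.grid(grids, stringsAsFactors = FALSE)
  p <- ifelse(joint$.Y == "1", model$prior, 1 - model$prior)
  for (nm in names(model$variables)) {
    probs <- model$cpts[[nm]]$probs
    col <- ifelse(joint$.Y == "1", "p_event", "p_noevent")
    p <- p * probs[cbind(joint[[nm]], col)]
  }
  keep <- rep(TRUE, nrow(joint))
  for (nm in names(asg)) keep <- keep & joint[[nm]] == asg[[nm]]
  num <- sum(p[keep & joint$.Y == "1"])
  den <- sum(p[keep])
  num / den
}
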