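#' Normalized likelihood of an observed state
#'
#' Impact metric for a single piece of evidence:
#' \deqn{NL(e) = \frac{P(e \mid Y=1)}{P(e)}, \qquad
#'       P(e) = P(Y{=}1) P(e \mid Y{=}1) + P(Y{=}0) P(e \mid Y{=}0),}
#' which equals the posterior-to-prior ratio `P(Y=1|e)/P(Y=1)` for that item
#' alone. `NL > 1` marks a risk-increasing finding, `NL < 1` a protective
#' one, `NL = 1` a finding carrying no association with the outcome.
#'
#' @param model A `calibra_model`.
#' @param variable Variable name.
#' @param state Observed state label.
#' @return A single positive numeric.
#' @export
normalized_likelihood <- function(model, variable, state) {
  validate_evidence(model, stats::setNames(state, variable))
  probs <- model$cpts[[variable]]$probs
  p1 <- probs[state, "p_event"]
  p0 <- probs[state, "p_noevent"]
  marginal <- model$prior * p1 + (1 - model$prior) * p0
  p1 / marginal
}

#' Impact report for observed evidence
#'
#' Ranks every observed item by its normalized likelihood, labelling each as
#' risk-increasing (NL > 1), protective (NL < 1) or neutral.
#'
#' @param model A `calibra_model`.
#' @param evidence Non-empty evidence (see [predict_risk()]).
#' @param neutral_tol Half-width of the band around NL = 1 labelled neutral.
#' @return A data frame of class `impact_report` with columns `variable`,
#'   `state`, `nl`, `direction`, sorted by `nl` descending.
#' @export
impact_report <- function(model, evidence, neutral_tol = 1e-9) {
  asg <- validate_evidence(model, evidence)
  if (length(asg) == 0L) {
    stop("impact_report requires at least one observed variable", call. = FALSE)
  }
  nl <- vapply(names(asg), function(nm) {
    normalized_likelihood(model, nm, asg[[nm]])
  }, numeric(1))
  direction <- ifelse(abs(nl - 1) <= neutral_tol, "neutral",
                      ifelse(nl > 1, "risk-increasing", "protective"))
  out <- data.frame(variable = names(asg), state = unname(asg),
                    nl = unname(nl), direction = direction,
                    row.names = NULL)
  out <- out[order(-out$nl), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("impact_report", "data.frame")
  out
}

# binary entropy of P(Y=1)=p, base 2; 0 log 0 = 0
binary_entropy <- function(p) {
  terms <- cbind(p, 1 - p)
  -rowSums(ifelse(terms > 0, terms * log2(terms), 0))
}

#' Value of information for one unmeasured variable
#'
#' Expected reduction in outcome entropy from measuring one additional
#' variable, given the evidence already observed:
#' \deqn{VOI(X) = H(Y \mid E) - \sum_s P(X{=}s \mid E)\, H(Y \mid E, X{=}s),}
#' in bits. Under the model this equals the conditional mutual information
#' `I(Y; X | E)` and is non-negative, zero exactly when `X` carries no
#' information about the outcome. A candidate that is already part of the
#' evidence has zero value and is reported as such with a message rather
#' than an error.
#'
#' @param model A `calibra_model`.
#' @param evidence Current evidence (may be empty).
#' @param candidate Name of the unmeasured variable to evaluate.
#' @return Non-negative numeric (bits).
#' @export
value_of_information <- function(model, evidence = evidence_vector(), candidate) {
  asg <- validate_evidence(model, evidence)
  if (is.null(model$variables[[candidate]])) {
    stop("unknown candidate variable '", candidate, "'", call. = FALSE)
  }
  if (candidate %in% names(asg)) {
    message("candidate '", candidate, "' is already observed; VOI = 0")
    return(0)
  }
  post <- predict_risk(model, asg)$posterior
  h_before <- binary_entropy(post)
  probs <- model$cpts[[candidate]]$probs
  # P(X=s | E) = post * P(s|Y=1) + (1-post) * P(s|Y=0)
  p_state <- post * probs[, "p_event"] + (1 - post) * probs[, "p_noevent"]
  llr <- log(probs[, "p_event"]) - log(probs[, "p_noevent"])
  post_given_s <- stats::plogis(stats::qlogis(post) + llr)
  h_after <- sum(p_state * binary_entropy(post_given_s))
  max(h_before - h_after, 0)
}

#' Ranked, indexed value-of-information report
#'
#' Computes the value of information for each candidate variable and indexes
#' the values either to the largest one (`mode = "max"`, top entry indexed
#' to 1) or to the residual outcome entropy `H(Y|E)`
#' (`mode = "residual-entropy"`, each entry the fraction of remaining
#' uncertainty the measurement would remove). The ranking is identical under
#' both modes.
#'
#' @param model A `calibra_model`.
#' @param evidence Current evidence.
#' @param candidates Character vector of variable names; defaults to all
#'   model variables not in the evidence. Candidates already observed are
#'   dropped.
#' @param mode Normalization mode, `"max"` or `"residual-entropy"`.
#' @return A data frame of class `voi_report` with columns `variable`,
#'   `voi_bits`, `indexed_voi`, `rank`, and attribute `normalization_mode`;
#'   empty when every candidate is already observed.
#' @export
indexed_voi <- function(model, evidence = evidence_vector(),
                        candidates = NULL,
                        mode = c("max", "residual-entropy")) {
  mode <- match.arg(mode)
  asg <- validate_evidence(model, evidence)
  if (is.null(candidates)) {
    candidates <- setdiff(names(model$variables), names(asg))
  } else {
    candidates <- setdiff(candidates, names(asg))
  }
  if (length(candidates) == 0L) {
    out <- data.frame(variable = character(0), voi_bits = numeric(0),
                      indexed_voi = numeric(0), rank = integer(0))
    attr(out, "normalization_mode") <- mode
    class(out) <- c("voi_report", "data.frame")
    return(out)
  }
  voi <- vapply(candidates, function(nm) {
    value_of_information(model, asg, nm)
  }, numeric(1))
  denom <- if (mode == "max") {
    max(voi)
  } else {
    binary_entropy(predict_risk(model, asg)$posterior)
  }
  indexed <- if (denom > 0) voi / denom else voi * 0
  ord <- order(-voi)
  out <- data.frame(variable = candidates[ord], voi_bits = unname(voi[ord]),
                    indexed_voi = unname(indexed[ord]),
                    rank = seq_along(ord), row.names = NULL)
  attr(out, "normalization_mode") <- mode
  class(out) <- c("voi_report", "data.frame")
  out
}
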