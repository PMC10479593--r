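# shared fixtures, all generated in code

# two-variable toy model with hand-set CPTs
toy_model <- function(prior = 0.1) {
  vars <- list(
    variable_spec("marker", "binary", c("neg", "pos")),
    variable_spec("stage", "categorical", c("a", "b", "c"))
  )
  cpts <- list(
    marker = cbind(p_event = c(0.2, 0.8), p_noevent = c(0.8, 0.2)),
    stage = cbind(p_event = c(0.1, 0.3, 0.6), p_noevent = c(0.5, 0.3, 0.2))
  )
  nb_model(prior, vars, cpts)
}

# single-binary-variable model with given conditional P(pos|Y)
one_var_model <- function(prior, p1, p0) {
  vars <- list(variable_spec("x", "binary", c("neg", "pos")))
  nb_model(prior, vars,
           list(x = cbind(p_event = c(1 - p1, p1), p_noevent = c(1 - p0, p0))))
}

# random feasible (prior, exposure prevalence, OR) triple; any OR > 0 is
# feasible for a 2x2 table with fixed margins strictly inside (0,1)
random_or_triple <- function() {
  c(prior = runif(1, 0.02, 0.6), q = runif(1, 0.05, 0.9),
    or = exp(runif(1, -2, 2)))
}

# random feasible (prior, q, RR) triple: RR (p - q) < 1 - q keeps b > 0
random_rr_triple <- function() {
  repeat {
    p <- runif(1, 0.02, 0.6); q <- runif(1, 0.05, 0.9)
    rr <- exp(runif(1, -1.5, 1.5))
    a <- rr * q / (1 - q + rr * q)
    b <- (q - p * a) / (1 - p)
    if (a > 1e-6 && a < 1 - 1e-6 && b > 1e-6 && b < 1 - 1e-6) {
      return(c(prior = p, q = q, rr = rr))
    }
  }
}

# random evidence subset drawn from a model's variables
random_evidence <- function(model, n_obs = NULL) {
  vnames <- names(model$variables)
  if (is.null(n_obs)) n_obs <- sample(0:length(vnames), 1)
  picked <- sample(vnames, n_obs)
  asg <- vapply(picked, function(nm) {
    sample(model$variables[[nm]]$states, 1)
  }, character(1))
  evidence_vector(as.list(asg))
}

# brute-force AUC: count concordant pos-neg pairs, ties half
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force conditional mutual information I(Y; X | E) in bits via the
# full joint, independent of the package's VOI path
brute_force_voi <- function(model, evidence, candidate) {
  asg <- if (inherits(evidence, "evidence_vector")) evidence$assignments else evidence
  h2 <- function(p) {
    p <- c(p, 1 - p)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  p_e <- enumerate_joint_posterior(model, asg)
  h_before <- h2(p_e)
  states <- model$variables[[candidate]]$states
  # P(X = s | E) via enumeration of the joint
  h_after <- 0
  for (s in states) {
    asg_s <- c(asg, stats::setNames(s, candidate))
    # joint weight of (E, X = s): run enumeration manually
    p_s_given_e <- enumerate_state_prob(model, asg, candidate, s)
    if (p_s_given_e > 0) {
      h_after <- h_after + p_s_given_e * h2(enumerate_joint_posterior(model, asg_s))
    }
  }
  h_before - h_after
}

# P(X = s | E) from the full joint
enumerate_state_prob <- function(model, asg, candidate, s) {
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
  sum(p[keep & joint[[candidate]] == s]) / sum(p[keep])
}
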