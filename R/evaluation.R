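# DeLong structural components (midrank algorithm).
# Returns list(auc, v10 (per-positive), v01 (per-negative)).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1) {
    stop("both outcome classes must be present to compute an AUC", call. = FALSE)
  }
}

#' ROC area under the curve with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen event
#' patient scores above a randomly chosen non-event patient, ties counted
#' one half. The 95\% confidence interval uses the DeLong structural-
#' components variance estimator, truncated to `[0, 1]`.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcomes, both classes present.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `roc_result` with fields `auc`, `ci_low`,
#'   `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  check_labels(labels)
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(auc = dc$auc,
         ci_low = max(0, dc$auc - z * sqrt(v)),
         ci_high = min(1, dc$auc + z * sqrt(v)),
         se = sqrt(v), n_pos = dc$m, n_neg = dc$n),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<ROC> AUC = %.4f (95%% CI %.4f-%.4f; %d events, %d non-events)\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Nonparametric comparison of two risk scores evaluated on the same
#' patients. The variance of `AUC_a - AUC_b` uses the DeLong structural
#' components of both scores, including their covariance induced by the
#' pairing; the two-sided p-value comes from the normal reference
#' distribution. Identical scores (zero variance, zero difference) return
#' `p = 1` by convention.
#'
#' @param scores_a,scores_b Numeric scores on the same patients.
#' @param labels 0/1 outcomes.
#' @return An object of class `delong_comparison` with fields `auc_a`,
#'   `auc_b`, `delta_auc` (a - b), `variance`, `z`, `p_value`,
#'   `effective_n`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]; labels <- labels[ok]
  check_labels(labels)
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  v <- max(v, 0)
  delta <- da$auc - db$auc
  if (v == 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(v)
  }
  p <- if (v == 0 && delta == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(
    list(auc_a = da$auc, auc_b = db$auc, delta_auc = delta, variance = v,
         z = z, p_value = p, effective_n = length(labels)),
    class = "delong_comparison"
  )
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("<DeLong> AUC_a = %.4f, AUC_b = %.4f, delta = %+.4f, p = %.4g (n = %d)\n",
              x$auc_a, x$auc_b, x$delta_auc, x$p_value, x$effective_n))
  invisible(x)
}

#' Fixed-order non-inferiority then superiority test
#'
#' Sequential gatekeeping comparison of a new score against a reference on
#' the same patients. Step 1 (non-inferiority): the one-sided 95\%
#' confidence lower bound of `AUC_new - AUC_ref` must lie entirely above
#' the margin `-sigma`. Step 2 (superiority), evaluated only if step 1
#' passes so the type-I error is not inflated by multiplicity: the point
#' difference must reach `superiority_threshold` and the two-sided DeLong
#' p-value must fall below `alpha`. An alternative reading of the
#' non-inferiority bound — on the new score's own AUC rather than on the
#' difference — is available via `ni_on_difference = FALSE`, in which case
#' the lower confidence bound of `AUC_new` must exceed `AUC_ref - sigma`.
#'
#' @param scores_new,scores_ref Paired scores.
#' @param labels 0/1 outcomes.
#' @param sigma Non-inferiority margin on the AUC scale (default 0.05).
#' @param superiority_threshold Minimum AUC difference for superiority
#'   (default 0.05).
#' @param alpha Significance level (default 0.05, one-sided for step 1).
#' @param ni_on_difference Logical; test non-inferiority on the paired AUC
#'   difference (default) or on the new score's AUC alone.
#' @return An object of class `gatekeeping_verdict` with logical fields
#'   `noninferior`, `superior`, the `delong` comparison, and `notes`.
#' @export
gatekeeping_test <- function(scores_new, scores_ref, labels,
                             sigma = 0.05, superiority_threshold = 0.05,
                             alpha = 0.05, ni_on_difference = TRUE) {
  cmp <- delong_paired(scores_new, scores_ref, labels)
  z1 <- stats::qnorm(1 - alpha)
  if (ni_on_difference) {
    lower <- cmp$delta_auc - z1 * sqrt(cmp$variance)
    noninferior <- lower > -sigma
    ni_note <- sprintf("one-sided %d%% lower bound of delta AUC = %.4f vs margin %.4f",
                       round(100 * (1 - alpha)), lower, -sigma)
  } else {
    rn <- roc_auc(scores_new, labels, conf_level = 1 - 2 * alpha)
    rr <- roc_auc(scores_ref, labels)
    lower <- rn$ci_low
    noninferior <- lower > rr$auc - sigma
    ni_note <- sprintf("one-sided %d%% lower bound of new AUC = %.4f vs reference - margin = %.4f",
                       round(100 * (1 - alpha)), lower, rr$auc - sigma)
  }
  superior <- FALSE
  sup_note <- "superiority not tested (non-inferiority failed; alpha not spent)"
  if (noninferior) {
    superior <- cmp$delta_auc >= superiority_threshold && cmp$p_value < alpha
    sup_note <- sprintf("delta AUC = %+.4f (threshold %.2f), DeLong p = %.4g",
                        cmp$delta_auc, superiority_threshold, cmp$p_value)
  }
  structure(
    list(noninferior = noninferior, superior = superior,
         margin = sigma, superiority_threshold = superiority_threshold,
         alpha = alpha, delong = cmp,
         notes = c(noninferiority = ni_note, superiority = sup_note)),
    class = "gatekeeping_verdict"
  )
}

#' @export
print.gatekeeping_verdict <- function(x, ...) {
  cat(sprintf("<gatekeeping> noninferior = %s, superior = %s\n",
              x$noninferior, x$superior))
  cat("  ", x$notes[["noninferiority"]], "\n", sep = "")
  cat("  ", x$notes[["superiority"]], "\n", sep = "")
  invisible(x)
}

#' Calibration table by score quantiles
#'
#' Partitions the cohort into `k` near-equal bins by predicted score
#' (quintiles by default), ties broken by stable rank so duplicated scores
#' never create empty bins, and tabulates per-bin mean predicted risk and
#' observed outcome incidence, plus the risk ratios between adjacent bins
#' (`observed_{i+1} / observed_i`, `NA`-flagged when the denominator is 0).
#'
#' @param predicted Numeric predicted risks.
#' @param labels 0/1 observed outcomes.
#' @param k Number of bins (default 5).
#' @return An object of class `calibration_table`: a list with data frame
#'   `bins` (`bin`, `n`, `score_min`, `score_max`, `mean_predicted`,
#'   `observed`) and numeric `adjacent_risk_ratios`.
#' @export
calibration_by_quantile <- function(predicted, labels, k = 5) {
  stopifnot(length(predicted) == length(labels), k >= 1,
            length(predicted) >= k)
  ok <- !is.na(predicted) & !is.na(labels)
  predicted <- predicted[ok]; labels <- labels[ok]
  n <- length(predicted)
  ord <- order(predicted, seq_len(n))  # stable rank
  bin_of_rank <- ceiling(seq_len(n) * k / n)
  bin <- integer(n)
  bin[ord] <- bin_of_rank
  bins <- do.call(rbind, lapply(seq_len(k), function(b) {
    idx <- bin == b
    data.frame(bin = b, n = sum(idx),
               score_min = min(predicted[idx]),
               score_max = max(predicted[idx]),
               mean_predicted = mean(predicted[idx]),
               observed = mean(labels[idx]))
  }))
  rr <- bins$observed[-1] / bins$observed[-k]
  rr[!is.finite(rr)] <- NA_real_
  structure(list(bins = bins, adjacent_risk_ratios = rr, k = k),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration> %d bins\n", x$k))
  print(x$bins, row.names = FALSE)
  cat("adjacent risk ratios:",
      paste(signif(x$adjacent_risk_ratios, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Incidence density with exact Poisson confidence interval
#'
#' Events per person-year with the exact (chi-square based) Poisson 95\%
#' confidence interval:
#' `lower = qchisq(0.025, 2 events) / (2 T)`,
#' `upper = qchisq(0.975, 2 events + 2) / (2 T)`;
#' the lower limit is 0 when no events occurred.
#'
#' @param events Non-negative integer count of events.
#' @param person_years Positive person-time at risk.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `incidence_density` with fields `events`,
#'   `person_years`, `rate`, `ci_low`, `ci_high`.
#' @export
incidence_density <- function(events, person_years, conf_level = 0.95) {
  if (events < 0 || person_years <= 0) {
    stop("incidence_density requires events >= 0 and person_years > 0",
         call. = FALSE)
  }
  a <- 1 - conf_level
  low <- if (events == 0) 0 else stats::qchisq(a / 2, 2 * events) / (2 * person_years)
  high <- stats::qchisq(1 - a / 2, 2 * events + 2) / (2 * person_years)
  structure(
    list(events = as.integer(events), person_years = person_years,
         rate = events / person_years, ci_low = low, ci_high = high),
    class = "incidence_density"
  )
}

#' @export
print.incidence_density <- function(x, ...) {
  cat(sprintf("<incidence> %.4f events/person-year (95%% CI %.4f-%.4f; %d events, %.1f py)\n",
              x$rate, x$ci_low, x$ci_high, x$events, x$person_years))
  invisible(x)
}
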