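#' Create a literature effect-size record
#'
#' One published finding linking an exposure state of a risk factor to the
#' cardiovascular outcome, expressed as an odds ratio (OR), risk ratio (RR)
#' or hazard ratio (HR) with a confidence interval, the study sample size and
#' follow-up, and flags marking populations excluded from pooling.
#'
#' @param study_id Study identifier.
#' @param variable Risk-factor name.
#' @param exposure_state State label the effect refers to (vs the reference).
#' @param measure One of `"OR"`, `"RR"`, `"HR"`.
#' @param point Point estimate (positive).
#' @param ci_low,ci_high 95\% confidence limits, `ci_low <= point <= ci_high`.
#' @param n Study sample size (integer >= 1).
#' @param followup_years Study follow-up in years (positive).
#' @param pediatric,rrt,other_disease Population flags; records with any flag
#'   set are excluded by [filter_studies()].
#' @return An object of class `effect_record`.
#' @export
effect_record <- function(study_id, variable, exposure_state,
                          measure = c("OR", "RR", "HR"),
                          point, ci_low = point, ci_high = point,
                          n, followup_years,
                          pediatric = FALSE, rrt = FALSE, other_disease = FALSE) {
  measure <- match.arg(measure)
  stopifnot(point > 0, ci_low > 0, ci_high > 0, n >= 1, followup_years > 0)
  if (ci_low > point || point > ci_high) {
    stop("effect record '", study_id, "': requires ci_low <= point <= ci_high",
         call. = FALSE)
  }
  structure(
    list(study_id = as.character(study_id), variable = as.character(variable),
         exposure_state = as.character(exposure_state), measure = measure,
         point = as.numeric(point), ci_low = as.numeric(ci_low),
         ci_high = as.numeric(ci_high), n = as.integer(n),
         followup_years = as.numeric(followup_years),
         pediatric = isTRUE(pediatric), rrt = isTRUE(rrt),
         other_disease = isTRUE(other_disease)),
    class = "effect_record"
  )
}

#' Read an evidence table from CSV
#'
#' Expected columns: `study_id, variable, exposure_state, measure, point,
#' ci_low, ci_high, n, followup_years, pediatric, rrt, other_disease`.
#' Missing flag columns default to `FALSE`; missing CI columns default to the
#' point estimate.
#'
#' @param path Path to a CSV file.
#' @return A list of [effect_record()] objects.
#' @export
read_evidence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "variable", "exposure_state", "measure",
                "point", "n", "followup_years")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("evidence table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  get_col <- function(col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  ci_low <- get_col("ci_low", NA_real_)
  ci_high <- get_col("ci_high", NA_real_)
  ped <- get_col("pediatric", FALSE)
  rrt <- get_col("rrt", FALSE)
  oth <- get_col("other_disease", FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    effect_record(
      study_id = df$study_id[i], variable = df$variable[i],
      exposure_state = df$exposure_state[i], measure = df$measure[i],
      point = df$point[i],
      ci_low = if (is.na(ci_low[i])) df$point[i] else ci_low[i],
      ci_high = if (is.na(ci_high[i])) df$point[i] else ci_high[i],
      n = df$n[i], followup_years = df$followup_years[i],
      pediatric = isTRUE(as.logical(ped[i])), rrt = isTRUE(as.logical(rrt[i])),
      other_disease = isTRUE(as.logical(oth[i]))
    )
  })
}

#' Filter studies eligible for pooling
#'
#' Retains records with at least 1 year of follow-up and drops studies of
#' pediatric populations, patients on renal replacement therapy, and other
#' disease populations. Input order is preserved; an empty result is allowed.
#'
#' @param records List of [effect_record()] objects.
#' @return The eligible subset, in the original order.
#' @export
filter_studies <- function(records) {
  keep <- vapply(records, function(r) {
    r$followup_years >= 1 && !r$pediatric && !r$rrt && !r$other_disease
  }, logical(1))
  records[keep]
}

#' Pool effect sizes across studies
#'
#' Fixed-effect pooling on the log scale with normalized study sample size as
#' the weight: the pooled log effect is `sum_i (n_i / sum_j n_j) * log(point_i)`.
#' All records must concern the same variable, exposure state and effect
#' measure; mixing measures (e.g. OR with RR) is rejected.
#'
#' @param records Non-empty list of [effect_record()] objects for one
#'   variable/state/measure combination.
#' @return An object of class `pooled_effect` with fields `variable`,
#'   `exposure_state`, `measure`, `pooled_log_effect`, `pooled_effect`
#'   (the exponentiated value), `weights` (normalized, summing to 1) and
#'   `n_studies`.
#' @export
pool_effect_sizes <- function(records) {
  if (length(records) < 1L) stop("no records to pool", call. = FALSE)
  measures <- vapply(records, `[[`, character(1), "measure")
  if (length(unique(measures)) > 1L) {
    stop("measure heterogeneity: cannot pool mixed effect measures (",
         paste(unique(measures), collapse = ", "), ")", call. = FALSE)
  }
  vars <- vapply(records, `[[`, character(1), "variable")
  sts <- vapply(records, `[[`, character(1), "exposure_state")
  if (length(unique(vars)) > 1L || length(unique(sts)) > 1L) {
    stop("all records must concern the same variable and exposure state",
         call. = FALSE)
  }
  n <- vapply(records, `[[`, integer(1), "n")
  w <- n / sum(n)
  log_points <- log(vapply(records, `[[`, numeric(1), "point"))
  pooled <- sum(w * log_points)
  structure(
    list(variable = vars[[1]], exposure_state = sts[[1]], measure = measures[[1]],
         pooled_log_effect = pooled, pooled_effect = exp(pooled),
         weights = stats::setNames(w, vapply(records, `[[`, character(1), "study_id")),
         n_studies = length(records)),
    class = "pooled_effect"
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("<pooled effect> %s [%s]: %s = %.4f (%d studies)\n",
              x$variable, x$exposure_state, x$measure, x$pooled_effect,
              x$n_studies))
  invisible(x)
}
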