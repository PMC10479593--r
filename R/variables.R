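#' Define a model variable
#'
#' A variable in the risk network is either binary, categorical, or a
#' continuous measurement discretized into ordered states by cut-points.
#' Continuous variables use half-open binning: a value in `[cut_i, cut_{i+1})`
#' maps to state `i + 1`, values below the first cut-point map to the first
#' state and values at or above the last cut-point map to the last state.
#'
#' @param name Variable identifier (string).
#' @param kind One of `"binary"`, `"categorical"`, `"continuous"`.
#' @param states Character vector of ordered state labels (at least 2).
#' @param cutpoints Strictly ascending numeric thresholds, length
#'   `length(states) - 1`; required for continuous variables, must be `NULL`
#'   otherwise.
#' @param units Free-text measurement units (continuous variables).
#' @param reference_state The state treated as baseline when inverting
#'   published effect sizes; defaults to the first state.
#' @param alt_cutpoints Optional named list of alternative measurement
#'   channels, each a cut-point vector of the same length as `cutpoints`
#'   mapping a different assay scale onto the same states (e.g. urinary
#'   albumin-to-creatinine ratio as an alternative to 24-hour urine protein).
#' @return An object of class `calibra_variable`.
#' @export
variable_spec <- function(name, kind = c("binary", "categorical", "continuous"),
                          states, cutpoints = NULL, units = "",
                          reference_state = states[[1]], alt_cutpoints = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (length(states) < 2L) {
    stop("variable '", name, "': at least 2 states are required", call. = FALSE)
  }
  if (anyDuplicated(states)) {
    stop("variable '", name, "': duplicate state labels", call. = FALSE)
  }
  if (kind == "continuous") {
    if (is.null(cutpoints) || length(cutpoints) != length(states) - 1L) {
      stop("variable '", name, "': continuous variables need length(states) - 1 cutpoints",
           call. = FALSE)
    }
    cutpoints <- as.numeric(cutpoints)
    if (any(diff(cutpoints) <= 0)) {
      stop("variable '", name, "': cutpoints must be strictly ascending", call. = FALSE)
    }
  } else if (!is.null(cutpoints)) {
    stop("variable '", name, "': cutpoints are only valid for continuous variables",
         call. = FALSE)
  }
  if (kind == "binary" && length(states) != 2L) {
    stop("variable '", name, "': binary variables have exactly 2 states", call. = FALSE)
  }
  if (!reference_state %in% states) {
    stop("variable '", name, "': reference_state must be one of the states", call. = FALSE)
  }
  if (!is.null(alt_cutpoints)) {
    stopifnot(is.list(alt_cutpoints), !is.null(names(alt_cutpoints)))
    for (ch in names(alt_cutpoints)) {
      cp <- as.numeric(alt_cutpoints[[ch]])
      if (length(cp) != length(states) - 1L || any(diff(cp) <= 0)) {
        stop("variable '", name, "': alternative channel '", ch,
             "' needs ", length(states) - 1L, " strictly ascending cutpoints",
             call. = FALSE)
      }
      alt_cutpoints[[ch]] <- cp
    }
  }
  structure(
    list(name = name, kind = kind, states = states, cutpoints = cutpoints,
         units = units, reference_state = reference_state,
         alt_cutpoints = alt_cutpoints),
    class = "calibra_variable"
  )
}

#' @export
print.calibra_variable <- function(x, ...) {
  cat(sprintf("<variable> %s (%s%s)\n", x$name, x$kind,
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  cat("  states:", paste(x$states, collapse = " | "), "\n")
  if (!is.null(x$cutpoints)) {
    cat("  cutpoints:", paste(x$cutpoints, collapse = ", "), "\n")
  }
  cat("  reference:", x$reference_state, "\n")
  invisible(x)
}

#' Map a continuous measurement to its discrete state
#'
#' Half-open binning: values below the first cut-point go to the first state,
#' a value equal to a cut-point goes to the bin above it, and values at or
#' above the last cut-point go to the last state. Non-finite values (NA, NaN,
#' Inf) are treated as missing and return `NA_character_`.
#'
#' @param value Numeric vector of raw measurements.
#' @param spec A continuous [variable_spec()].
#' @param channel Optional name of an alternative measurement channel whose
#'   cut-points (see `alt_cutpoints`) are used instead of the primary ones.
#' @return Character vector of state labels (`NA` where `value` is not finite).
#' @export
discretize <- function(value, spec, channel = NULL) {
  stopifnot(inherits(spec, "calibra_variable"))
  if (spec$kind != "continuous") {
    stop("discretize() requires a continuous variable, got '", spec$kind, "'",
         call. = FALSE)
  }
  cuts <- spec$cutpoints
  if (!is.null(channel)) {
    if (is.null(spec$alt_cutpoints) || !channel %in% names(spec$alt_cutpoints)) {
      stop("variable '", spec$name, "' has no measurement channel '", channel, "'",
           call. = FALSE)
    }
    cuts <- spec$alt_cutpoints[[channel]]
  }
  idx <- findInterval(value, cuts, left.open = FALSE) + 1L
  out <- spec$states[idx]
  out[!is.finite(value)] <- NA_character_
  out
}

# look up a spec by name in a list of calibra_variable
find_variable <- function(variables, name) {
  for (v in variables) if (v$name == name) return(v)
  NULL
}
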