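#' Save a model to JSON
#'
#' Serializes the prior, variable definitions and conditional probability
#' tables to a JSON document. Probabilities are written with 17 significant
#' digits so that a load/save round trip reproduces every probability
#' bit-exactly.
#'
#' @param model A `calibra_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  validate_model(model)
  doc <- list(
    prior = model$prior,
    variables = lapply(unname(model$variables), function(v) {
      out <- list(name = v$name, kind = v$kind, states = v$states,
                  units = v$units, reference_state = v$reference_state)
      if (!is.null(v$cutpoints)) out$cutpoints <- v$cutpoints
      if (!is.null(v$alt_cutpoints)) out$alt_cutpoints <- v$alt_cutpoints
      out
    }),
    cpts = lapply(model$cpts, function(ct) {
      list(states = rownames(ct$probs),
           p_event = unname(ct$probs[, "p_event"]),
           p_noevent = unname(ct$probs[, "p_noevent"]))
    }),
    metadata = model$metadata
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a model from JSON
#'
#' Reads a document written by [save_model()] (or hand-edited in the same
#' dialect), validates the schema and all model invariants, and returns the
#' model. Schema violations name the offending fields.
#'
#' @param path Path to a model JSON file.
#' @return A `calibra_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  for (field in c("prior", "variables", "cpts")) {
    if (is.null(doc[[field]])) {
      stop("model file schema violation: missing top-level field '", field, "'",
           call. = FALSE)
    }
  }
  if (!is.numeric(doc$prior) || doc$prior <= 0 || doc$prior >= 1) {
    stop("model file schema violation: 'prior' must be a number in (0,1)",
         call. = FALSE)
  }
  variables <- lapply(doc$variables, function(v) {
    for (field in c("name", "kind", "states", "reference_state")) {
      if (is.null(v[[field]])) {
        stop("model file schema violation: variable entry missing '", field, "'",
             call. = FALSE)
      }
    }
    variable_spec(
      name = v$name, kind = v$kind, states = unlist(v$states),
      cutpoints = if (!is.null(v$cutpoints)) unlist(v$cutpoints),
      units = if (!is.null(v$units)) v$units else "",
      reference_state = v$reference_state,
      alt_cutpoints = v$alt_cutpoints
    )
  })
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  for (nm in names(variables)) {
    ct <- doc$cpts[[nm]]
    if (is.null(ct) || is.null(ct$p_event) || is.null(ct$p_noevent)) {
      stop("model file schema violation: missing or incomplete CPT for variable '",
           nm, "'", call. = FALSE)
    }
  }
  cpt_list <- lapply(names(variables), function(nm) {
    ct <- doc$cpts[[nm]]
    cbind(p_event = unlist(ct$p_event), p_noevent = unlist(ct$p_noevent))
  })
  names(cpt_list) <- names(variables)
  nb_model(prior = doc$prior, variables = variables, cpt_list = cpt_list,
           metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}
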