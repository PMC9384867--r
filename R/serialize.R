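MODEL_SCHEMA <- "enmpair-maxent/1"

#' Serialize a fitted model to a structured text document
#'
#' Writes every field needed to reproduce predictions — feature
#' definitions (kinds, parents, knots), per-variable training ranges,
#' coefficients, penalties, rm, fc, normalizer and entropy — as
#' schema-versioned JSON.
#'
#' @param model an `enm_maxent`.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_maxent_model <- function(model, path) {
  stopifnot(inherits(model, "enm_maxent"))
  doc <- list(
    schema = MODEL_SCHEMA,
    fc = model$fc, rm = model$rm, m = model$m,
    n_background = model$n_background,
    logZ = model$logZ, H = model$H,
    objective = model$objective, gain = model$gain,
    vars = model$features$vars,
    scale = lapply(model$features$scale, function(s)
      list(min = s[["min"]], max = s[["max"]])),
    defs = lapply(model$features$defs, function(d) {
      out <- list(kind = d$kind, var = d$var)
      if (!is.na(d$var2)) out$var2 <- d$var2
      if (!is.na(d$knot)) out$knot <- d$knot
      out
    }),
    beta = as.list(model$beta),
    lambda = as.numeric(model$lambda))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path path written by [write_maxent_model()].
#' @return an `enm_maxent` equivalent to the original for prediction
#'   and projection.
#' @export
read_maxent_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, MODEL_SCHEMA))
    stopf("unsupported model schema '%s' (expected %s)",
          doc$schema %||% "<missing>", MODEL_SCHEMA)
  defs <- lapply(doc$defs, function(d)
    list(kind = d$kind, var = d$var,
         var2 = if (is.null(d$var2)) NA_character_ else d$var2,
         knot = if (is.null(d$knot)) NA_real_ else as.numeric(d$knot)))
  scale <- lapply(doc$scale, function(s)
    c(min = as.numeric(s$min), max = as.numeric(s$max)))
  feats <- structure(list(defs = defs, scale = scale, fc = doc$fc,
                          vars = unlist(doc$vars)),
                     class = "enm_features")
  feats$names <- feature_names(feats)
  beta <- unlist(doc$beta)
  structure(
    list(features = feats, beta = beta,
         lambda = as.numeric(unlist(doc$lambda)), rm = doc$rm,
         fc = doc$fc, m = doc$m, n_background = doc$n_background,
         logZ = doc$logZ, H = doc$H, objective = doc$objective,
         gain = doc$gain, iters = NA_integer_),
    class = "enm_maxent")
}
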