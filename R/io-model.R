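# Model serialization: versioned JSON with dense parameter blocks in
# documented order. Block cells are flattened with the first animal of the
# subset varying fastest (the array linear layout); keys are ordered by
# subset size then lexicographically, so output is byte-stable.

MODEL_FORMAT_VERSION <- "groupmaxent-model-1"

#' Write a fitted model to a JSON file
#'
#' @param model A [maxent()] model.
#' @param path Output path.
#' @return `path` invisibly.
#' @seealso [read_maxent()]
#' @export
write_maxent <- function(model, path) {
  stopifnot(inherits(model, "maxent"))
  keys <- names(model$params)
  ord <- order(lengths(lapply(keys, key_subset)), keys)
  params <- lapply(model$params[keys[ord]], function(b) as.vector(b))
  obj <- list(format = MODEL_FORMAT_VERSION,
              n_animals = model$n_animals, n_zones = model$n_zones,
              order = model$order, epsilon = model$epsilon,
              sample_count = model$sample_count,
              zone_legend = as.character(attr(model$table, "legend") %||%
                                           character(0)),
              log_partition = model$log_partition,
              params = params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_maxent()]
#'
#' The joint table and log-partition value are recomputed from the parameter
#' blocks on load.
#'
#' @param path File path.
#' @return A [maxent()] model object.
#' @export
read_maxent <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT_VERSION))
    abort_parse(sprintf("unrecognized model format: %s", obj$format %||% "<none>"))
  Z <- as.integer(obj$n_zones)
  params <- lapply(obj$params, function(v) {
    k <- round(log(length(v)) / log(Z))
    array(as.numeric(v), dim = rep(Z, k))
  })
  m <- new_maxent(params, n_animals = as.integer(obj$n_animals), n_zones = Z,
                  epsilon = as.numeric(obj$epsilon %||% 0),
                  sample_count = as.integer(obj$sample_count %||% 0L))
  m$order <- as.integer(obj$order)
  if (length(obj$zone_legend))
    attr(m$table, "legend") <- zone_legend(obj$zone_legend)
  m
}
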