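# Model serialization: human-readable JSON holding the layer structure,
# neuron coefficients at full precision and the normalization parameters.

MODEL_SCHEMA_VERSION <- 1L

model_to_list <- function(model) {
  norm <- model$normalization
  list(
    schema_version = MODEL_SCHEMA_VERSION,
    n_raw_inputs = model$n_raw_inputs,
    output_neuron = model$output_neuron,
    growth = model$growth %||% "compose",
    target_transform = model$target_transform %||% "none",
    pool_cap = model$pool_cap %||% 24L,
    normalization = list(
      columns = norm$columns,
      min = unname(norm$min),
      max = unname(norm$max),
      constant = unname(norm$constant)
    ),
    layers = lapply(model$layers, function(layer) {
      lapply(layer$neurons, function(n) {
        list(input_i = n$input_i, input_j = n$input_j,
             coefficients = unname(n$coefficients),
             criterion_score = n$criterion_score)
      })
    })
  )
}

#' Write a GMDH model to a JSON file
#'
#' Coefficients are written at full double precision so that reading the
#' file back reproduces the model bit-for-bit.
#'
#' @param model a `gmdh_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmdh_model <- function(model, path) {
  stopifnot(inherits(model, "gmdh_model"))
  jsonlite::write_json(model_to_list(model), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a GMDH model from a JSON file
#'
#' @param path file written by [write_gmdh_model()].
#' @return a `gmdh_model`.
#' @export
read_gmdh_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$schema_version) ||
      obj$schema_version != MODEL_SCHEMA_VERSION)
    abort(sprintf("unsupported model schema version: %s",
                  obj$schema_version %||% "missing"))
  norm <- structure(
    list(min = as.numeric(obj$normalization$min),
         max = as.numeric(obj$normalization$max),
         constant = as.logical(obj$normalization$constant),
         columns = unlist(obj$normalization$columns)),
    class = "kerma_normalization"
  )
  layers <- lapply(obj$layers, function(layer) {
    structure(list(neurons = lapply(layer, function(n) {
      cf <- as.numeric(n$coefficients)
      names(cf) <- paste0("c", 1:6)
      structure(list(input_i = as.integer(n$input_i),
                     input_j = as.integer(n$input_j),
                     coefficients = cf,
                     criterion_score = as.numeric(n$criterion_score)),
                class = "gmdh_neuron")
    })), class = "gmdh_layer")
  })
  structure(
    list(layers = layers, normalization = norm,
         n_raw_inputs = as.integer(obj$n_raw_inputs),
         output_neuron = as.integer(obj$output_neuron),
         growth = obj$growth %||% "compose",
         target_transform = obj$target_transform %||% "none",
         pool_cap = as.integer(obj$pool_cap %||% 24L)),
    class = "gmdh_model"
  )
}
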