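# Model checkpointing: one JSON document holding every per-modality
# parameter array plus the configuration, under a versioned schema field.

CHECKPOINT_SCHEMA <- 1L

#' Save / load a trained model
#'
#' @param model A `coembed_model` (or the `model` element of a `coembed_fit`).
#' @param path Output path (JSON).
#' @return `path` invisibly; `read_checkpoint()` returns a `coembed_model`.
#' @export
write_checkpoint <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("checkpointing requires the jsonlite package")
  ser_lin <- function(l) list(W = l$W, b = l$b, dim = dim(l$W))
  payload <- list(
    schema = CHECKPOINT_SCHEMA,
    config = unclass(model$config),
    modalities = lapply(model$params, function(p) list(
      d_m = p$d_m, h1 = p$h1, h2 = p$h2,
      enc = lapply(p$enc, ser_lin), dec = lapply(p$dec, ser_lin))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("checkpointing requires the jsonlite package")
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema) || payload$schema != CHECKPOINT_SCHEMA)
    abort("unrecognized checkpoint schema")
  cfg <- do.call(coembed_config, payload$config[
    setdiff(names(payload$config), character())])
  de_lin <- function(l) list(W = matrix(unlist(l$W), l$dim[1], l$dim[2]),
                             b = as.numeric(l$b))
  params <- lapply(payload$modalities, function(p) list(
    enc = lapply(p$enc, de_lin), dec = lapply(p$dec, de_lin),
    d_m = as.integer(p$d_m), h1 = as.integer(p$h1), h2 = as.integer(p$h2)))
  structure(list(params = params, config = cfg), class = "coembed_model")
}
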