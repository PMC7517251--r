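# portable text serialization for models and sample sets

#' Save and load RBM models
#'
#' Models round-trip through JSON: weights, biases, inverse temperature and
#' training metadata.
#'
#' @param model An [rbm()].
#' @param path File path.
#' @return `write_rbm()` returns the path invisibly; `read_rbm()` the model.
#' @export
write_rbm <- function(model, path) {
  stopifnot(inherits(model, "rbm"))
  obj <- list(W = model$W, b_h = model$b_h, b_v = model$b_v,
              beta = model$beta, meta = model$meta,
              package_version = as.character(packageVersion("boltzcode")))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rbm
#' @export
read_rbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- rbm(obj$W, obj$b_h, obj$b_v, beta = obj$beta)
  out$meta <- as.list(obj$meta)
  out
}

#' Save and load pattern datasets
#'
#' Observations are stored one per line as bit strings (most significant bit
#' = first raster cell), with metadata in a JSON header line.
#'
#' @param data A [pattern_dataset()].
#' @param path File path.
#' @return `write_pattern_dataset()` returns the path invisibly;
#'   `read_pattern_dataset()` the dataset.
#' @export
write_pattern_dataset <- function(data, path) {
  stopifnot(inherits(data, "pattern_dataset"))
  header <- jsonlite::toJSON(c(list(n_units = data$n_units), data$meta),
                             auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(paste0("#", header), pattern_strings(data$x)), path)
  invisible(path)
}

#' @rdname write_pattern_dataset
#' @export
read_pattern_dataset <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^#", "", lines[[1]]))
  x <- pattern_from_string(lines[-1])
  pattern_dataset(x, meta = meta[setdiff(names(meta), "n_units")])
}
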