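CHECKPOINT_VERSION <- 1L

#' Save a trained model to a single-file checkpoint
#'
#' The file holds a 4-byte little-endian header length, a JSON header
#' (format version, vocabulary, configuration, ordered weight names and
#' shapes), then the weight values as little-endian doubles in header order.
#' The round-trip is bit-exact.
#'
#' @param model A `pep_lstm` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pep_lstm"))
  shapes <- purrr::map(model$weights, function(w) {
    if (is.matrix(w)) dim(w) else length(w)
  })
  header <- jsonlite::toJSON(list(
    format_version = CHECKPOINT_VERSION,
    symbols = model$vocab$symbols,
    config = unclass(model$config),
    weight_names = names(model$weights),
    shapes = shapes,
    window = model$window
  ), auto_unbox = TRUE, digits = NA)
  raw_header <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(raw_header), con, size = 4L, endian = "little")
  writeBin(raw_header, con)
  for (w in model$weights) {
    writeBin(as.numeric(w), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @param expect_layers Optional layer count to enforce; a mismatch is a
#'   load error naming the layer expectation.
#' @return A `pep_lstm` model (with an empty loss trace).
#' @export
load_checkpoint <- function(path, expect_layers = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("checkpoint '%s' does not exist", path),
          class = "pepgen_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  if (length(hlen) == 0L || hlen <= 0L) {
    abort("truncated checkpoint: missing header", class = "pepgen_io_error")
  }
  raw_header <- readBin(con, raw(), n = hlen)
  if (length(raw_header) < hlen) {
    abort("truncated checkpoint: incomplete header", class = "pepgen_io_error")
  }
  header <- jsonlite::fromJSON(rawToChar(raw_header), simplifyVector = TRUE)
  if (!identical(as.integer(header$format_version), CHECKPOINT_VERSION)) {
    abort(sprintf("unsupported checkpoint format version %s",
                  header$format_version), class = "pepgen_io_error")
  }
  cfg <- do.call(model_config, header$config[
    setdiff(names(header$config), character(0))
  ])
  if (!is.null(expect_layers) && cfg$layers != expect_layers) {
    abort(sprintf(
      "checkpoint has %d LSTM layer(s) but %d expected (field 'layers')",
      cfg$layers, expect_layers
    ), class = "pepgen_io_error")
  }
  weights <- list()
  for (i in seq_along(header$weight_names)) {
    nm <- header$weight_names[i]
    shape <- header$shapes[[nm]]
    n_vals <- prod(shape)
    vals <- readBin(con, numeric(), n = n_vals, size = 8L, endian = "little")
    if (length(vals) < n_vals) {
      abort(sprintf("truncated checkpoint: weight '%s' incomplete", nm),
            class = "pepgen_io_error")
    }
    weights[[nm]] <- if (length(shape) == 2L) matrix(vals, shape[1], shape[2])
                     else vals
  }
  vocab <- pep_vocabulary()
  if (!identical(vocab$symbols, as.character(header$symbols))) {
    abort("checkpoint vocabulary does not match the package vocabulary",
          class = "pepgen_io_error")
  }
  structure(list(vocab = vocab, config = cfg, weights = weights,
                 trace = tibble(epoch = integer(0), train_loss = numeric(0),
                                val_loss = numeric(0)),
                 window = header$window),
            class = "pep_lstm")
}
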