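#' k-fold cross-validation over an architecture grid
#'
#' Rows are shuffled once with `base_seed` and split into `k` contiguous
#' folds. For every configuration in the grid and every fold, model weights
#' are re-initialized with `seed = base_seed + fold` (so no residual
#' knowledge carries across folds), the model is trained on the remaining
#' folds and scored on the held-out fold after every epoch. The selected
#' architecture minimizes, across the grid, the minimum over epochs of the
#' fold-averaged validation loss.
#'
#' @param x A corpus tibble.
#' @param grid A list of [model_config()] objects.
#' @param k Number of folds (default 5).
#' @param base_seed Seed for the fold shuffle and per-fold reseeding.
#' @return An object of class `pep_cv` with a `traces` tibble
#'   (architecture, fold, epoch, train_loss, val_loss), the `selected`
#'   architecture label, `fold_seeds`, and the grid.
#' @export
cross_validate <- function(x, grid, k = 5L, base_seed = 42L) {
  x <- validate_corpus(x, allow_empty = FALSE)
  if (length(grid) == 0L) {
    abort("architecture grid is empty", class = "pepgen_config_error")
  }
  if (k < 2L || nrow(x) < k) {
    abort("need k >= 2 and at least k sequences", class = "pepgen_config_error")
  }
  n <- nrow(x)
  ord <- with_seed_(base_seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[ord] <- cut(seq_len(n), breaks = k, labels = FALSE)
  fold_seeds <- base_seed + seq_len(k)
  window <- max(nchar(x$sequence)) + 2L
  traces <- purrr::map(grid, function(cfg) {
    label <- sprintf("%dx%d", cfg$layers, cfg$units)
    purrr::map(seq_len(k), function(fold) {
      cfg_fold <- cfg
      cfg_fold$seed <- base_seed + fold
      fit <- train_lstm(x[fold_of != fold, , drop = FALSE], cfg_fold,
                        validation = x[fold_of == fold, , drop = FALSE],
                        window = window)
      dplyr::mutate(fit$trace, architecture = label, fold = fold,
                    .before = 1L)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  mean_val <- traces |>
    dplyr::summarise(val = mean(.data$val_loss),
                     .by = c("architecture", "epoch")) |>
    dplyr::summarise(best = min(.data$val), .by = "architecture")
  selected <- mean_val$architecture[which.min(mean_val$best)]
  structure(list(traces = traces, selected = selected,
                 fold_seeds = fold_seeds, grid = grid, k = k),
            class = "pep_cv")
}

#' @export
print.pep_cv <- function(x, ...) {
  cat(sprintf("<pep_cv> %d architectures x %d folds; selected: %s\n",
              length(x$grid), x$k, x$selected))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch loss trace of a trained model
#'
#' @param x A `pep_lstm` model.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss` (nats).
#' @export
tidy.pep_lstm <- function(x, ...) x$trace

#' One-row model summary
#'
#' @param x A `pep_lstm` model.
#' @param ... Unused.
#' @return Tibble with architecture, parameter count and final losses.
#' @export
glance.pep_lstm <- function(x, ...) {
  tibble(
    layers = x$config$layers,
    units = x$config$units,
    n_parameters = sum(purrr::map_int(x$weights, length)),
    epochs = nrow(x$trace),
    final_train_loss = if (nrow(x$trace)) utils::tail(x$trace$train_loss, 1)
                       else NA_real_,
    final_val_loss = if (nrow(x$trace)) utils::tail(x$trace$val_loss, 1)
                     else NA_real_
  )
}

#' Per-(architecture, fold, epoch) cross-validation traces
#'
#' @param x A `pep_cv` object.
#' @param ... Unused.
#' @return The traces tibble.
#' @export
tidy.pep_cv <- function(x, ...) x$traces

#' Architecture-level cross-validation summary
#'
#' @param x A `pep_cv` object.
#' @param ... Unused.
#' @return One row per architecture: best mean validation loss, its epoch,
#'   and whether it was selected.
#' @export
glance.pep_cv <- function(x, ...) {
  x$traces |>
    dplyr::summarise(val = mean(.data$val_loss),
                     .by = c("architecture", "epoch")) |>
    dplyr::summarise(best_val_loss = min(.data$val),
                     best_epoch = .data$epoch[which.min(.data$val)],
                     .by = "architecture") |>
    dplyr::mutate(selected = .data$architecture == x$selected)
}
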