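#' LSTM model configuration
#'
#' Hyperparameters of the character-level peptide language model. Defaults
#' are the production settings used for peptide generation: a two-layer
#' unidirectional LSTM with 256 memory units per layer, 30% and 45% dropout
#' on the first and second layer outputs, Adam with learning rate 0.02, a
#' fixed forget-gate bias of 1, and a 200-epoch budget.
#'
#' @param layers Number of LSTM layers (1 or 2).
#' @param units Memory units per layer.
#' @param dropout Per-layer dropout fractions in `[0, 1)`; recycled to
#'   `layers`.
#' @param learning_rate Adam learning rate.
#' @param forget_gate_bias Constant added to the forget-gate bias at
#'   initialization.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size; batches larger than the corpus run
#'   full-batch.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; the model is fully reproducible from it.
#' @param include_pad_loss Include padding-target positions in the loss
#'   (default `FALSE`; they are masked out).
#' @return A list of class `pep_model_config`.
#' @export
model_config <- function(layers = 2L, units = 256L, dropout = c(0.30, 0.45),
                         learning_rate = 0.02, forget_gate_bias = 1.0,
                         epochs = 200L, batch_size = 128L, seed = 42L,
                         include_pad_loss = FALSE) {
  if (!layers %in% c(1L, 2L)) {
    abort("layers must be 1 or 2", class = "pepgen_config_error")
  }
  dropout <- rep_len(dropout, layers)
  if (any(dropout < 0 | dropout >= 1)) {
    abort("dropout fractions must lie in [0, 1)", class = "pepgen_config_error")
  }
  if (units < 1L || epochs < 0L || learning_rate <= 0) {
    abort("units >= 1, epochs >= 0 and learning_rate > 0 required",
          class = "pepgen_config_error")
  }
  structure(list(layers = as.integer(layers), units = as.integer(units),
                 dropout = as.numeric(dropout),
                 learning_rate = as.numeric(learning_rate),
                 forget_gate_bias = as.numeric(forget_gate_bias),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 include_pad_loss = isTRUE(include_pad_loss)),
            class = "pep_model_config")
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# weights: per layer Wx (in_dim x 4U, gate order i|f|g|o), Wh (U x 4U),
# b (4U); head Wy (U x 22), by (22). Initialization consumes the current RNG
# stream (callers seed it).
init_lstm_weights <- function(cfg, vocab_size = 22L) {
  U <- cfg$units
  w <- list()
  in_dim <- vocab_size
  for (l in seq_len(cfg$layers)) {
    b <- numeric(4L * U)
    b[(U + 1L):(2L * U)] <- cfg$forget_gate_bias
    w[[paste0("Wx", l)]] <- glorot(in_dim, 4L * U)
    w[[paste0("Wh", l)]] <- glorot(U, 4L * U)
    w[[paste0("b", l)]] <- b
    in_dim <- U
  }
  w$Wy <- glorot(U, vocab_size)
  w$by <- numeric(vocab_size)
  w
}

onehot_rows <- function(tokens_col, K = 22L) {
  n <- length(tokens_col)
  m <- matrix(0, n, K)
  m[cbind(seq_len(n), tokens_col + 1L)] <- 1
  m
}

#' Categorical cross-entropy over one-hot targets
#'
#' Mean of `-sum(t_k * log(y_k))` (natural log, nats) over unmasked rows,
#' for one-hot targets `t` and row-stochastic predictions `y`.
#'
#' @param targets One-hot matrix (rows x classes).
#' @param predictions Row-stochastic matrix, same shape; rows must sum to 1
#'   within 1e-6.
#' @param mask Optional logical vector (one per row); `FALSE` rows are
#'   excluded from the mean.
#' @param epsilon Optional lower clip applied to predicted probabilities; by
#'   default a non-positive probability at a target position is an error
#'   rather than being silently clipped.
#' @return Mean loss in nats (non-negative scalar).
#' @export
#' @examples
#' cross_entropy(diag(22)[1, , drop = FALSE], matrix(1 / 22, 1, 22)) # log(22)
cross_entropy <- function(targets, predictions, mask = NULL, epsilon = NULL) {
  targets <- as.matrix(targets)
  predictions <- as.matrix(predictions)
  stopifnot(identical(dim(targets), dim(predictions)))
  rs <- rowSums(predictions)
  if (any(abs(rs - 1) > 1e-6)) {
    abort("prediction rows must sum to 1 within 1e-6",
          class = "pepgen_numeric_error")
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(targets))
  keep <- which(mask)
  if (length(keep) == 0L) return(0)
  p_target <- rowSums(targets[keep, , drop = FALSE] *
                        predictions[keep, , drop = FALSE])
  if (!is.null(epsilon)) {
    p_target <- pmax(p_target, epsilon)
  } else if (any(p_target <= 0)) {
    abort("predicted probability <= 0 at a target position",
          class = "pepgen_numeric_error")
  }
  mean(-log(p_target))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass over a token window. Returns per-step softmax probabilities
# and, when train = TRUE, all caches needed for backpropagation through time.
lstm_forward <- function(w, cfg, tokens, train = FALSE) {
  N <- nrow(tokens); T <- ncol(tokens); U <- cfg$units; L <- cfg$layers
  K <- ncol(w$Wy)
  h <- lapply(seq_len(L), function(l) matrix(0, N, U))
  cc <- lapply(seq_len(L), function(l) matrix(0, N, U))
  cache <- if (train) vector("list", T - 1L)
  probs <- vector("list", T - 1L)
  drop_masks <- vector("list", T - 1L)
  for (t in seq_len(T - 1L)) {
    x <- onehot_rows(tokens[, t], K)
    step <- if (train) vector("list", L)
    dm <- if (train) vector("list", L)
    for (l in seq_len(L)) {
      z <- x %*% w[[paste0("Wx", l)]] + h[[l]] %*% w[[paste0("Wh", l)]]
      z <- sweep(z, 2L, w[[paste0("b", l)]], "+")
      gi <- sigmoid(z[, 1:U, drop = FALSE])
      gf <- sigmoid(z[, (U + 1L):(2L * U), drop = FALSE])
      gg <- tanh(z[, (2L * U + 1L):(3L * U), drop = FALSE])
      go <- sigmoid(z[, (3L * U + 1L):(4L * U), drop = FALSE])
      c_new <- gf * cc[[l]] + gi * gg
      tc <- tanh(c_new)
      h_new <- go * tc
      if (train) {
        step[[l]] <- list(x = x, h_prev = h[[l]], c_prev = cc[[l]],
                          i = gi, f = gf, g = gg, o = go, c = c_new, tc = tc)
      }
      cc[[l]] <- c_new
      h[[l]] <- h_new
      out <- h_new
      if (train && cfg$dropout[l] > 0) {
        keep <- matrix(runif(N * U) >= cfg$dropout[l], N, U)
        out <- out * keep / (1 - cfg$dropout[l])
        dm[[l]] <- keep
      }
      x <- out
    }
    logits <- sweep(x %*% w$Wy, 2L, w$by, "+")
    probs[[t]] <- softmax_rows(logits)
    if (train) {
      step$head_in <- x
      cache[[t]] <- step
      drop_masks[[t]] <- dm
    }
  }
  list(probs = probs, cache = cache, drop_masks = drop_masks)
}

# masked mean next-token loss for a forward pass
lstm_loss_from_probs <- function(probs, tokens, loss_mask) {
  T <- ncol(tokens)
  total <- 0
  n_pos <- 0L
  for (t in seq_len(T - 1L)) {
    keep <- which(loss_mask[, t])
    if (length(keep) == 0L) next
    tgt <- tokens[keep, t + 1L] + 1L
    p <- probs[[t]][cbind(keep, tgt)]
    total <- total + sum(-log(pmax(p, 1e-300)))
    n_pos <- n_pos + length(keep)
  }
  if (n_pos == 0L) return(0)
  total / n_pos
}

# loss given weights (no dropout); used for validation and gradient checks
lstm_loss <- function(w, cfg, tokens, loss_mask) {
  fw <- lstm_forward(w, cfg, tokens, train = FALSE)
  lstm_loss_from_probs(fw$probs, tokens, loss_mask)
}

# forward + BPTT gradients for one minibatch (dropout active)
lstm_grad <- function(w, cfg, tokens, loss_mask) {
  N <- nrow(tokens); T <- ncol(tokens); U <- cfg$units; L <- cfg$layers
  K <- ncol(w$Wy)
  fw <- lstm_forward(w, cfg, tokens, train = TRUE)
  n_pos <- sum(loss_mask[, seq_len(T - 1L), drop = FALSE])
  g <- lapply(w, function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m))
              else numeric(length(m)))
  names(g) <- names(w)
  if (n_pos == 0L) {
    return(list(loss = 0,
                grads = g))
  }
  loss <- lstm_loss_from_probs(fw$probs, tokens, loss_mask)
  dh_next <- lapply(seq_len(L), function(l) matrix(0, N, U))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, N, U))
  for (t in rev(seq_len(T - 1L))) {
    step <- fw$cache[[t]]
    dm <- fw$drop_masks[[t]]
    p <- fw$probs[[t]]
    dlogits <- p
    tgt <- tokens[, t + 1L] + 1L
    dlogits[cbind(seq_len(N), tgt)] <- dlogits[cbind(seq_len(N), tgt)] - 1
    dlogits <- dlogits * (loss_mask[, t] / n_pos)
    g$Wy <- g$Wy + crossprod(step$head_in, dlogits)
    g$by <- g$by + colSums(dlogits)
    dout <- tcrossprod(dlogits, w$Wy)
    for (l in rev(seq_len(L))) {
      s <- step[[l]]
      if (!is.null(dm[[l]])) dout <- dout * dm[[l]] / (1 - cfg$dropout[l])
      dh <- dout + dh_next[[l]]
      do_ <- dh * s$tc
      dc <- dc_next[[l]] + dh * s$o * (1 - s$tc^2)
      di <- dc * s$g
      df <- dc * s$c_prev
      dg <- dc * s$i
      dc_next[[l]] <- dc * s$f
      da <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      g[[paste0("Wx", l)]] <- g[[paste0("Wx", l)]] + crossprod(s$x, da)
      g[[paste0("Wh", l)]] <- g[[paste0("Wh", l)]] + crossprod(s$h_prev, da)
      g[[paste0("b", l)]] <- g[[paste0("b", l)]] + colSums(da)
      dh_next[[l]] <- tcrossprod(da, w[[paste0("Wh", l)]])
      dout <- tcrossprod(da, w[[paste0("Wx", l)]])
    }
  }
  list(loss = loss, grads = g)
}

adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(w)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g[[k]]^2
    w[[k]] <- w[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(w = w, state = state)
}

#' Train the LSTM peptide language model
#'
#' Next-token training on padded windows: the input at position `t` is token
#' `t` and the target is token `t + 1`, the first input being the start
#' token. Optimized with Adam at the configured learning rate; dropout is
#' applied per layer during training only. The run is fully reproducible
#' from `cfg$seed`.
#'
#' @param x A corpus tibble or a `pep_encoded` batch.
#' @param cfg A [model_config()].
#' @param validation Optional corpus tibble or `pep_encoded` batch scored
#'   (without dropout) after every epoch.
#' @param window Window length forwarded to [encode_corpus()] when `x` is a
#'   corpus.
#' @return An object of class `pep_lstm`: vocabulary, config, trained
#'   weights, and a per-epoch loss trace (nats) retrievable with
#'   [tidy.pep_lstm()].
#' @export
train_lstm <- function(x, cfg = model_config(), validation = NULL,
                       window = NULL) {
  vocab <- pep_vocabulary()
  batch <- if (inherits(x, "pep_encoded")) x
           else encode_corpus(x, vocab, window = window,
                              mask_pad = !cfg$include_pad_loss)
  if (nrow(batch$tokens) == 0L) {
    abort("training batch is empty", class = "pepgen_config_error")
  }
  val <- NULL
  if (!is.null(validation)) {
    val <- if (inherits(validation, "pep_encoded")) validation
           else encode_corpus(validation, vocab,
                              window = max(ncol(batch$tokens),
                                           max(nchar(validation$sequence)) + 2L),
                              mask_pad = !cfg$include_pad_loss)
  }
  with_seed_(cfg$seed, {
    w <- init_lstm_weights(cfg, length(vocab$symbols))
    state <- adam_init(w)
    N <- nrow(batch$tokens)
    bs <- min(cfg$batch_size, N)
    trace <- tibble(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = bs)
      ep_loss <- 0
      ep_pos <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + bs - 1L, N)]
        gb <- lstm_grad(w, cfg, batch$tokens[idx, , drop = FALSE],
                        batch$loss_mask[idx, , drop = FALSE])
        if (!is.finite(gb$loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d", ep),
                class = "pepgen_numeric_error")
        }
        upd <- adam_step(w, gb$grads, state, cfg$learning_rate)
        w <- upd$w
        state <- upd$state
        npos <- sum(batch$loss_mask[idx, -ncol(batch$loss_mask), drop = FALSE])
        ep_loss <- ep_loss + gb$loss * npos
        ep_pos <- ep_pos + npos
      }
      vl <- if (is.null(val)) NA_real_
            else lstm_loss(w, cfg, val$tokens, val$loss_mask)
      trace <- dplyr::bind_rows(trace, tibble(
        epoch = ep, train_loss = ep_loss / max(ep_pos, 1), val_loss = vl
      ))
    }
    structure(list(vocab = vocab, config = cfg, weights = w, trace = trace,
                   window = ncol(batch$tokens)),
              class = "pep_lstm")
  })
}

#' @export
print.pep_lstm <- function(x, ...) {
  cat(sprintf("<pep_lstm> %d-layer LSTM, %d units, %d epochs trained\n",
              x$config$layers, x$config$units, nrow(x$trace)))
  if (nrow(x$trace) > 0L) {
    cat(sprintf("  final training loss: %.4f nats\n",
                utils::tail(x$trace$train_loss, 1)))
  }
  invisible(x)
}

#' Sample novel peptides from a trained model
#'
#' Autoregressive sampling primed with the start token: softmax logits are
#' divided by `temperature` before drawing; a draw ends at the end token or
#' at `max_len` residues. `temperature = 0` selects the argmax (greedy
#' decoding). Draws containing non-canonical tokens (a mid-sequence pad) or
#' of zero length are discarded, so fewer than `n` peptides may return;
#' duplicates and training-set matches are removed downstream by
#' [dedupe_against()].
#'
#' @param model A trained [train_lstm()] model.
#' @param n Number of raw draws.
#' @param temperature Softmax temperature (>= 0).
#' @param max_len Maximum residues per draw.
#' @param seed Integer sampling seed.
#' @return A corpus tibble with `provenance = "generated"`.
#' @export
sample_peptides <- function(model, n, temperature = 1.0, max_len = 15L,
                            seed = 1L) {
  stopifnot(inherits(model, "pep_lstm"))
  if (temperature < 0) {
    abort("temperature must be >= 0", class = "pepgen_config_error")
  }
  vocab <- model$vocab
  if (n == 0L) return(corpus(character(), character(), "generated"))
  w <- model$weights
  cfg <- model$config
  U <- cfg$units; L <- cfg$layers; K <- length(vocab$symbols)
  with_seed_(seed, {
    h <- lapply(seq_len(L), function(l) matrix(0, n, U))
    cc <- lapply(seq_len(L), function(l) matrix(0, n, U))
    tok <- rep(vocab$pad, n)
    done <- rep(FALSE, n)
    drawn <- matrix(NA_integer_, n, max_len + 1L)
    for (step in seq_len(max_len + 1L)) {
      x <- onehot_rows(tok, K)
      for (l in seq_len(L)) {
        z <- x %*% w[[paste0("Wx", l)]] + h[[l]] %*% w[[paste0("Wh", l)]]
        z <- sweep(z, 2L, w[[paste0("b", l)]], "+")
        gi <- sigmoid(z[, 1:U, drop = FALSE])
        gf <- sigmoid(z[, (U + 1L):(2L * U), drop = FALSE])
        gg <- tanh(z[, (2L * U + 1L):(3L * U), drop = FALSE])
        go <- sigmoid(z[, (3L * U + 1L):(4L * U), drop = FALSE])
        cc[[l]] <- gf * cc[[l]] + gi * gg
        h[[l]] <- go * tanh(cc[[l]])
        x <- h[[l]]
      }
      logits <- sweep(x %*% w$Wy, 2L, w$by, "+")
      if (temperature == 0) {
        nxt <- max.col(logits, ties.method = "first") - 1L
      } else {
        p <- softmax_rows(logits / temperature)
        u <- runif(n)
        cum <- t(apply(p, 1L, cumsum))
        nxt <- max.col(cum >= u, ties.method = "first") - 1L
      }
      drawn[!done, step] <- nxt[!done]
      done <- done | drawn[, step] %in% vocab$eos
      tok <- nxt
      if (all(done)) break
    }
    seqs <- apply(drawn, 1L, function(row) {
      row <- row[!is.na(row)]
      stop_at <- which(row == vocab$eos)[1]
      if (!is.na(stop_at)) row <- row[seq_len(stop_at - 1L)]
      if (length(row) > max_len) row <- row[seq_len(max_len)]
      if (any(row >= 20L)) return(NA_character_)  # mid-sequence pad: invalid
      paste(vocab$symbols[row + 1L], collapse = "")
    })
    keep <- !is.na(seqs) & nzchar(seqs)
    corpus(sprintf("gen_%05d", which(keep)), seqs[keep], "generated")
  })
}

#' Remove duplicates and training-set matches from generated peptides
#'
#' Drops internal duplicate sequences (keeping the first occurrence) and any
#' sequence string-equal to one in the reference corpus.
#'
#' @param generated,reference Corpus tibbles.
#' @return The deduplicated generated corpus.
#' @export
dedupe_against <- function(generated, reference) {
  generated <- validate_corpus(generated)
  reference <- validate_corpus(reference)
  generated |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE) |>
    dplyr::filter(!.data$sequence %in% reference$sequence)
}
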