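test_that("categorical cross-entropy matches analytic values and the oracle", {
  onehot <- function(k, K = 22) { z <- matrix(0, 1, K); z[1, k] <- 1; z }
  uniform <- matrix(1 / 22, 1, 22)
  expect_equal(cross_entropy(onehot(3), uniform), log(22), tolerance = 1e-12)
  expect_equal(cross_entropy(onehot(3), onehot(3)), 0)

  set.seed(31)
  for (i in 1:20) {
    n <- 5
    p <- matrix(rexp(n * 22), n)
    p <- p / rowSums(p)
    t_idx <- sample(22, n, TRUE)
    tg <- matrix(0, n, 22)
    tg[cbind(1:n, t_idx)] <- 1
    mask <- runif(n) > 0.3
    if (!any(mask)) mask[1] <- TRUE
    expect_equal(cross_entropy(tg, p, mask),
                 oracle_cross_entropy(tg, p, mask), tolerance = 1e-10)
  }

  bad <- matrix(c(0.9, 0.2, rep(0, 20)), 1)   # rows don't sum to 1
  expect_error(cross_entropy(onehot(1), bad), class = "pepgen_numeric_error")
  zerop <- matrix(c(0, 1, rep(0, 20)), 1)
  expect_error(cross_entropy(onehot(1), zerop),
               class = "pepgen_numeric_error")
  expect_equal(cross_entropy(onehot(1), zerop, epsilon = 1e-12),
               -log(1e-12))
})

test_that("analytic BPTT gradients agree with central finite differences", {
  syn <- synth_corpus(4, c(4, 6), seed = 11)
  cfg <- model_config(layers = 2, units = 5, dropout = c(0, 0), epochs = 1,
                      seed = 3)
  batch <- encode_corpus(syn)
  w <- pepgen:::with_seed_(3, pepgen:::init_lstm_weights(cfg, 22))
  g <- pepgen:::lstm_grad(w, cfg, batch$tokens, batch$loss_mask)$grads
  set.seed(9)
  for (k in names(w)) {
    for (i in sample(length(w[[k]]), min(3, length(w[[k]])))) {
      e <- 1e-5
      wp <- w; wp[[k]][i] <- wp[[k]][i] + e
      wm <- w; wm[[k]][i] <- wm[[k]][i] - e
      num <- (pepgen:::lstm_loss(wp, cfg, batch$tokens, batch$loss_mask) -
                pepgen:::lstm_loss(wm, cfg, batch$tokens, batch$loss_mask)) /
        (2 * e)
      expect_equal(g[[k]][i], num, tolerance = 1e-4,
                   info = sprintf("weight %s[%d]", k, i))
    }
  }
})

test_that("softmax head output is row-stochastic", {
  syn <- synth_corpus(6, c(5, 8), seed = 2)
  cfg <- model_config(layers = 1, units = 8, dropout = 0, epochs = 2, seed = 5)
  m <- train_lstm(syn, cfg)
  batch <- encode_corpus(syn)
  fw <- pepgen:::lstm_forward(m$weights, cfg, batch$tokens)
  for (p in fw$probs) {
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  }
})

test_that("training is deterministic, and epochs = 0 returns the trace empty", {
  syn <- synth_corpus(8, c(5, 8), seed = 4)
  cfg <- model_config(layers = 1, units = 12, dropout = 0.2, epochs = 15,
                      seed = 99, learning_rate = 0.02)
  m1 <- train_lstm(syn, cfg)
  m2 <- train_lstm(syn, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$weights, m2$weights)

  cfg0 <- model_config(layers = 1, units = 12, epochs = 0, seed = 99)
  m0 <- train_lstm(syn, cfg0)
  expect_equal(nrow(m0$trace), 0L)
  w_init <- pepgen:::with_seed_(99, pepgen:::init_lstm_weights(cfg0, 22))
  expect_identical(m0$weights, w_init)
})

test_that("cross-validation produces k traces per architecture and a
           recomputable argmin selection", {
  syn <- synth_corpus(25, c(6, 9), motif = "KWL", seed = 8)
  grid <- list(
    model_config(layers = 1, units = 6, dropout = 0, epochs = 4, seed = 1),
    model_config(layers = 1, units = 10, dropout = 0, epochs = 4, seed = 1)
  )
  cv <- cross_validate(syn, grid, k = 5, base_seed = 17)
  traces <- tidy(cv)
  expect_equal(nrow(dplyr::distinct(traces, architecture, fold)), 10L)
  expect_length(unique(cv$fold_seeds), 5L)

  # oracle recomputation of the argmin from the emitted traces
  mean_val <- aggregate(val_loss ~ architecture + epoch, traces, mean)
  best <- aggregate(val_loss ~ architecture, mean_val, min)
  expect_equal(cv$selected, best$architecture[which.min(best$val_loss)])

  cv2 <- cross_validate(syn, grid, k = 5, base_seed = 17)
  expect_identical(tidy(cv2), traces)

  expect_error(cross_validate(syn, list(), k = 5),
               class = "pepgen_config_error")
})

test_that("sampling is seeded, canonical, and length-bounded", {
  syn <- synth_corpus(8, c(5, 8), motif = "KW", seed = 4)
  cfg <- model_config(layers = 1, units = 12, dropout = 0, epochs = 40,
                      seed = 3, learning_rate = 0.02)
  m <- train_lstm(syn, cfg)
  expect_equal(nrow(sample_peptides(m, 0)), 0L)
  s1 <- sample_peptides(m, 40, temperature = 1, max_len = 9, seed = 5)
  s2 <- sample_peptides(m, 40, temperature = 1, max_len = 9, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(nchar(s1$sequence) <= 9))
  expect_true(all(strsplit(paste(s1$sequence, collapse = ""), "")[[1]] %in%
                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_true(all(s1$provenance == "generated"))
})

test_that("dedupe removes internal duplicates and training matches", {
  gen <- corpus(c("g1", "g2", "g3"),
                c(strrep("A", 9), strrep("A", 9), strrep("C", 9)),
                "generated")
  ref <- corpus("r1", strrep("C", 9), "training")
  out <- dedupe_against(gen, ref)
  expect_equal(out$sequence, strrep("A", 9))

  disjoint <- corpus("g9", strrep("W", 9), "generated")
  expect_equal(dedupe_against(disjoint, ref), disjoint)

  # set-arithmetic oracle on planted duplicates
  set.seed(21)
  pool <- unique(vapply(rep(10, 40), random_peptide, character(1)))
  draws <- sample(pool, 60, replace = TRUE)
  refseqs <- sample(pool, 10)
  gen2 <- corpus(sprintf("g%03d", seq_along(draws)), draws, "generated")
  ref2 <- corpus(sprintf("r%03d", seq_along(refseqs)), refseqs, "training")
  expect_equal(nrow(dedupe_against(gen2, ref2)),
               length(setdiff(unique(draws), refseqs)))
})

test_that("checkpoints round-trip bit-exactly and fail loudly when damaged", {
  syn <- synth_corpus(6, c(5, 7), seed = 14)
  cfg <- model_config(layers = 2, units = 7, dropout = c(0.1, 0.1),
                      epochs = 3, seed = 23)
  m <- train_lstm(syn, cfg)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_identical(back$weights, m$weights)
  expect_identical(back$vocab$symbols, m$vocab$symbols)
  expect_identical(back$config, m$config)

  # identical sampling behaviour after the round-trip
  expect_identical(sample_peptides(back, 10, seed = 2),
                   sample_peptides(m, 10, seed = 2))

  # truncation
  full <- readBin(f, raw(), file.size(f))
  writeBin(full[1:(length(full) - 50)], f)
  err <- expect_error(load_checkpoint(f), class = "pepgen_io_error")
  expect_match(conditionMessage(err), "truncated")

  # layer-count expectation
  save_checkpoint(m, f)
  err2 <- expect_error(load_checkpoint(f, expect_layers = 1),
                       class = "pepgen_io_error")
  expect_match(conditionMessage(err2), "layer")
})
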