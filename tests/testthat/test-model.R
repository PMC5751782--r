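# Network-level behaviour: configuration validation, closed-form checks,
# determinism, loss decrease and the label decoding rules. Heavier
# whole-pipeline properties live in test-acceptance.R.

make_fit <- function(docs, lexicon, config = tiny_config()) {
  mcnn(docs, lexicon = lexicon, config = config)
}

test_that("configuration validates shape arithmetic", {
  expect_error(mcnn_config(window = 12L), "odd")
  # 13 - 5*2 = 3 positions left: valid
  expect_silent(mcnn_config(n_conv_layers = 5L))
  # 13 - 7*2 < 1: impossible
  expect_error(mcnn_config(n_conv_layers = 7L), "positions")
  expect_error(mcnn_config(dropout = 1), "dropout")
})

test_that("flatten length follows the valid-convolution shrinkage", {
  # 3 layers of width-3 valid convolutions: 13 -> 11 -> 9 -> 7; 7*100 = 700
  expect_equal(mcnn:::flat_dim(mcnn_config()), 700L)
  expect_equal(mcnn:::flat_dim(mcnn_config(n_conv_layers = 4L)), 500L)
  cfg <- tiny_config()   # window 5, 1 layer, 8 filters: (5-2)*8
  expect_equal(mcnn:::flat_dim(cfg), 24L)
})

test_that("softmax probabilities obey the closed forms", {
  p <- label_probs(c(0, 0, 0))$p_main
  expect_equal(p, rep(1 / 3, 3L))
  p <- label_probs(c(log(2), 0, 0))$p_main
  expect_equal(p, c(0.5, 0.25, 0.25))
  # shift invariance
  s <- c(1.3, -0.2, 7)
  expect_equal(label_probs(s)$p_main, label_probs(s + 100)$p_main)
  # sums to 1 within 1e-9 for random scores
  set.seed(1)
  for (i in 1:50) {
    out <- label_probs(stats::rnorm(3, sd = 10), stats::rnorm(9, sd = 10))
    expect_lt(abs(sum(out$p_main) - 1), 1e-9)
    expect_lt(abs(sum(out$p_aux) - 1), 1e-9)
    expect_true(all(out$p_main >= 0) && all(out$p_aux >= 0))
  }
  expect_error(label_probs(c(NaN, 0, 0)), "finite")
})

test_that("zero output weights give zero scores and uniform per-instance J", {
  cfg <- tiny_config(dropout = 0)
  s <- list(tokens = normalize_numbers(tokenize("aa bb cc dd")),
            labels = c("B", "I", "O", "O"))
  v <- build_vocabs(list(s))
  enc <- mcnn:::encode_corpus(list(s), v, window = cfg$window)
  params <- mcnn:::nn_init_params(cfg, v)
  params$Wm[] <- 0; params$bm[] <- 0
  params$Wa[] <- 0; params$ba[] <- 0
  batch <- mcnn:::batch_rows(enc, seq_len(enc$n))
  fwd <- mcnn:::nn_forward(params, batch, cfg)
  expect_true(all(fwd$Sm == 0) && all(fwd$Sa == 0))
  # J per instance = ln(1/3) + ln(1/9) under the uniform model
  nll <- mcnn:::nn_nll(fwd, batch, cfg)
  expect_equal(-nll / enc$n, log(1 / 3) + log(1 / 9), tolerance = 1e-12)
})

test_that("the log likelihood is additive over instance batches", {
  cfg <- tiny_config(dropout = 0)
  s <- list(tokens = normalize_numbers(tokenize("aa bb cc dd ee ff")),
            labels = c("B", "I", "O", "B", "O", "O"))
  v <- build_vocabs(list(s))
  enc <- mcnn:::encode_corpus(list(s), v, window = cfg$window)
  params <- mcnn:::nn_init_params(cfg, v)
  nll_of <- function(rows) {
    b <- mcnn:::batch_rows(enc, rows)
    mcnn:::nn_nll(mcnn:::nn_forward(params, b, cfg), b, cfg)
  }
  expect_equal(nll_of(1:6), nll_of(1:2) + nll_of(3:6), tolerance = 1e-10)
})

test_that("dropping the MLS term reduces the loss to 3-way cross-entropy", {
  cfg_off <- tiny_config(dropout = 0, mls = FALSE)
  s <- list(tokens = normalize_numbers(tokenize("aa bb cc dd")),
            labels = c("B", "O", "O", "B"))
  v <- build_vocabs(list(s))
  enc <- mcnn:::encode_corpus(list(s), v, window = cfg_off$window)
  params <- mcnn:::nn_init_params(cfg_off, v)
  batch <- mcnn:::batch_rows(enc, seq_len(enc$n))
  fwd <- mcnn:::nn_forward(params, batch, cfg_off)
  nll <- mcnn:::nn_nll(fwd, batch, cfg_off)
  # independent route: per-instance cross-entropy from the softmax output
  ce <- 0
  for (i in seq_len(enc$n)) {
    p <- label_probs(fwd$Sm[i, ])$p_main
    ce <- ce - log(p[batch$y[i]])
  }
  expect_equal(nll, ce, tolerance = 1e-10)
})

test_that("forward is deterministic out of training mode", {
  cfg <- tiny_config()
  s <- list(tokens = normalize_numbers(tokenize("aa bb cc")),
            labels = c("O", "B", "O"))
  v <- build_vocabs(list(s))
  enc <- mcnn:::encode_corpus(list(s), v, window = cfg$window)
  params <- mcnn:::nn_init_params(cfg, v)
  b <- mcnn:::batch_rows(enc, 1:3)
  f1 <- mcnn:::nn_forward(params, b, cfg, train = FALSE)
  f2 <- mcnn:::nn_forward(params, b, cfg, train = FALSE)
  expect_identical(f1$Sm, f2$Sm)
})

test_that("one epoch of SGD decreases the training loss", {
  syn <- small_synth(n_docs = 4L)
  sents <- mcnn:::as_labelled_sentences(syn$docs)[1:10]
  cfg <- tiny_config(dropout = 0, lr = 0.05, epochs = 1L)
  v <- build_vocabs(sents)
  enc <- mcnn:::encode_corpus(sents, v, window = cfg$window)
  params0 <- mcnn:::nn_init_params(cfg, v)
  batch <- mcnn:::batch_rows(enc, seq_len(enc$n))
  before <- mcnn:::nn_loss_grad(params0, batch, cfg, want_grad = FALSE)$loss
  lg <- mcnn:::nn_loss_grad(params0, batch, cfg)
  params1 <- mcnn:::nn_sgd_step(params0, lg$grads, cfg$lr, lg$n)
  after <- mcnn:::nn_loss_grad(params1, batch, cfg, want_grad = FALSE)$loss
  expect_lt(after, before)
})

test_that("fitting is reproducible under a fixed seed", {
  syn <- small_synth(n_docs = 5L)
  cfg <- tiny_config(epochs = 2L)
  f1 <- mcnn(syn$docs, lexicon = syn$lexicon, config = cfg)
  f2 <- mcnn(syn$docs, lexicon = syn$lexicon, config = cfg)
  expect_equal(f1$params, f2$params)
  expect_identical(predict(f1, syn$docs, type = "labels"),
                   predict(f2, syn$docs, type = "labels"))
})

test_that("an untrained zero-weight model predicts all O via the tie rule", {
  syn <- small_synth(n_docs = 2L)
  cfg <- tiny_config(epochs = 1L)
  fit <- mcnn(syn$docs, lexicon = syn$lexicon, config = cfg)
  fit$params$Wm[] <- 0
  fit$params$bm[] <- 0
  labs <- predict(fit, syn$docs, type = "labels")
  expect_true(all(unlist(labs) == "O"))
  # output length matches token count per sentence
  lens <- vapply(syn$docs[[1]]$sentences, nrow, integer(1))
  got <- vapply(labs[seq_along(lens)], length, integer(1))
  expect_equal(got, lens)
})

test_that("the pair-mode auxiliary head trains and scores correctly", {
  cfg <- tiny_config(dropout = 0, aux_mode = "pair")
  s <- list(tokens = normalize_numbers(tokenize("aa bb cc dd")),
            labels = c("B", "I", "O", "O"))
  v <- build_vocabs(list(s))
  enc <- mcnn:::encode_corpus(list(s), v, window = cfg$window)
  params <- mcnn:::nn_init_params(cfg, v)
  expect_equal(ncol(params$Wa), 6L)
  batch <- mcnn:::batch_rows(enc, seq_len(enc$n))
  fwd <- mcnn:::nn_forward(params, batch, cfg)
  params$Wa[] <- 0; params$ba[] <- 0
  fwd0 <- mcnn:::nn_forward(params, batch, cfg)
  nll0 <- mcnn:::nn_nll(fwd0, batch, cfg)
  # zero aux head: each of the two 3-way softmaxes contributes ln(1/3)
  main_part <- -sum(vapply(seq_len(enc$n), function(i) {
    log(label_probs(fwd0$Sm[i, ])$p_main[batch$y[i]])
  }, numeric(1)))
  expect_equal(nll0, main_part + enc$n * 2 * log(3), tolerance = 1e-10)
})

test_that("analytic gradients match finite differences in both aux modes", {
  err_joint <- mcnn_gradient_check(seed = 11L)
  expect_lt(as.numeric(err_joint), 1e-4)
  cfg <- mcnn_config(window = 5L, word_dim = 4L, char_dim = 3L, lex_dim = 2L,
                     char_cnn_filters = 2L, conv_filters = 2L,
                     n_conv_layers = 2L, dropout = 0, aux_mode = "pair")
  err_pair <- mcnn_gradient_check(config = cfg, seed = 12L)
  expect_lt(as.numeric(err_pair), 1e-4)
})
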