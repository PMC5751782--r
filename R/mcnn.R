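# User-facing model interface: configuration, the fitting function mcnn(),
# and S3 methods (print, summary, coef, predict, plot, logLik).

#' Model configuration
#'
#' Defaults follow the published hyper-parameter table for the NCBI setting:
#' context window 13, word embedding 200, character embedding 20, lexicon
#' embedding 5, character CNN window 3 with 20 filters, word-level
#' convolutions of window 3 with 100 filters, and 3 stacked convolutional
#' layers (use `n_conv_layers = 4` for the CDR setting). The word-level stack
#' is pooling-free; each convolution is "valid" (no padding) with ReLU, so the
#' 13-position window shrinks 13 -> 11 -> 9 -> 7 over three layers.
#'
#' Training hyper-parameters the original description leaves open are fixed
#' here as plain SGD on mean-per-batch gradients with learning rate 0.1
#' (chosen for stable convergence at CPU-scale epoch counts; see the methods
#' vignette), batch size 128, dropout 0.5 at both dropout sites (after
#' embedding concatenation and on character embeddings), and 10 epochs.
#'
#' @param window Odd context window size in tokens.
#' @param word_dim,char_dim,lex_dim Embedding dimensions.
#' @param char_cnn_window,char_cnn_filters Character-level CNN shape.
#' @param conv_window,conv_filters Word-level convolution shape.
#' @param n_conv_layers Number of stacked word-level convolutions; must leave
#'   at least one position: `window - n_conv_layers*(conv_window-1) >= 1`.
#' @param dropout Dropout rate in \[0, 1).
#' @param lr,batch_size,epochs SGD settings.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param mls If `TRUE` (default) the multiple label strategy auxiliary head
#'   is trained; if `FALSE` the objective is plain 3-way cross-entropy.
#' @param aux_mode `"joint"` (default): one softmax over the 9 (prev, next)
#'   label pairs; `"pair"`: two separate 3-way softmaxes.
#' @param use_char,use_lexicon Feature toggles (ablation axes).
#' @return A list of class `mcnn_config`.
#' @export
mcnn_config <- function(window = 13L, word_dim = 200L, char_dim = 20L,
                        lex_dim = 5L, char_cnn_window = 3L,
                        char_cnn_filters = 20L, conv_window = 3L,
                        conv_filters = 100L, n_conv_layers = 3L,
                        dropout = 0.5, lr = 0.1, batch_size = 128L,
                        epochs = 10L, seed = 1L, mls = TRUE,
                        aux_mode = c("joint", "pair"),
                        use_char = TRUE, use_lexicon = TRUE) {
  aux_mode <- match.arg(aux_mode)
  cfg <- list(window = as.integer(window), word_dim = as.integer(word_dim),
              char_dim = as.integer(char_dim), lex_dim = as.integer(lex_dim),
              char_cnn_window = as.integer(char_cnn_window),
              char_cnn_filters = as.integer(char_cnn_filters),
              conv_window = as.integer(conv_window),
              conv_filters = as.integer(conv_filters),
              n_conv_layers = as.integer(n_conv_layers),
              dropout = dropout, lr = lr,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed),
              mls = isTRUE(mls), aux_mode = aux_mode,
              use_char = isTRUE(use_char), use_lexicon = isTRUE(use_lexicon))
  validate_config(cfg)
  structure(cfg, class = "mcnn_config")
}

validate_config <- function(cfg) {
  if (cfg$window %% 2L == 0L) stop("window size must be odd")
  stopifnot(cfg$window > 0L, cfg$word_dim > 0L, cfg$char_dim > 0L,
            cfg$lex_dim > 0L, cfg$conv_filters > 0L,
            cfg$char_cnn_filters > 0L, cfg$n_conv_layers >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$lr > 0,
            cfg$batch_size >= 1L, cfg$epochs >= 1L)
  remaining <- cfg$window - cfg$n_conv_layers * (cfg$conv_window - 1L)
  if (remaining < 1L) {
    stop(sprintf(
      "window %d leaves no positions after %d valid convolutions of width %d",
      cfg$window, cfg$n_conv_layers, cfg$conv_window))
  }
  invisible(cfg)
}

# Accept documents (with $sentences [+ $mentions]) or pre-labelled sentences
# (list(tokens, labels)); return a flat list of labelled sentences.
as_labelled_sentences <- function(x) {
  if (length(x) == 0L) return(list())
  el <- x[[1]]
  if (!is.null(el$tokens)) return(x)                    # already sentences
  if (!is.null(el$doc_id) || !is.null(el$sentences)) {  # documents
    out <- list()
    for (d in x) {
      if (is.null(d$sentences)) d <- preprocess_document(d)
      out <- c(out, suppressWarnings(project_mentions_to_bio(d)))
    }
    return(out)
  }
  stop("expected a list of documents or of list(tokens, labels) sentences")
}

#' Fit the multiple-label convolutional tagger
#'
#' Trains the window-based convolutional BIO tagger by mini-batch SGD on the
#' negative log-likelihood `-J(theta)`, where `J` sums the log-probability of
#' each token's label under the main softmax head and (with MLS on) the
#' log-probability of its (previous, next) label pair under the auxiliary
#' head. The auxiliary head is a pure training signal; prediction uses the
#' main head only.
#'
#' @param train Training data: a list of documents (as from
#'   [read_pubtator()] / [gen_corpus()]) or of labelled sentences.
#' @param dev Optional development data of the same shape. When given,
#'   mention-level F on it is computed after every epoch and the parameters
#'   of the best epoch are returned; otherwise the final epoch's are.
#' @param lexicon Optional [mcnn_lexicon][build_lexicon()] supplying the
#'   dictionary feature (ignored when `config$use_lexicon` is `FALSE`).
#' @param word_vectors Optional path to pre-trained word vectors in the
#'   whitespace-delimited text format; absent words (and an absent file) are
#'   randomly initialized.
#' @param config An [mcnn_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `mcnn`.
#' @export
mcnn <- function(train, dev = NULL, lexicon = NULL, word_vectors = NULL,
                 config = mcnn_config(), verbose = FALSE) {
  validate_config(config)
  sents <- as_labelled_sentences(train)
  if (length(sents) == 0L) stop("empty training set")
  if (!config$use_lexicon) lexicon <- NULL
  vocab <- build_vocabs(sents)
  enc <- encode_corpus(sents, vocab, lexicon = lexicon, window = config$window)
  word_table <- if (is.null(word_vectors)) NULL else {
    load_word_vectors(word_vectors, vocab, dim = config$word_dim,
                      seed = config$seed)
  }
  params <- nn_init_params(config, vocab, word_table)

  dev_docs <- NULL
  if (!is.null(dev)) {
    dev_docs <- if (!is.null(dev[[1]]$tokens)) NULL else dev
    if (is.null(dev_docs)) {
      warning("dev data without documents: using final-epoch parameters",
              call. = FALSE)
    }
  }

  history <- data.frame(epoch = integer(0), nll = numeric(0),
                        dev_f = numeric(0))
  best <- list(f = -Inf, params = params, epoch = 0L)
  n_inst <- enc$n
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_inst)
      total <- 0
      for (b0 in seq(1L, n_inst, by = config$batch_size)) {
        rows <- ord[b0:min(b0 + config$batch_size - 1L, n_inst)]
        batch <- batch_rows(enc, rows)
        lg <- nn_loss_grad(params, batch, config, train = TRUE)
        params <- nn_sgd_step(params, lg$grads, config$lr, lg$n)
        total <- total + lg$loss
      }
      dev_f <- NA_real_
      if (!is.null(dev_docs)) {
        fit_obj <- new_mcnn(params, config, vocab, lexicon, NULL, epoch)
        pred <- predict(fit_obj, dev_docs, type = "mentions")
        gold <- do.call(rbind, lapply(dev_docs, function(d) d$mentions))
        dev_f <- mention_prf(pred, gold)$f
        if (dev_f >= best$f) best <- list(f = dev_f, params = params,
                                          epoch = epoch)
      }
      history <- rbind(history, data.frame(epoch = epoch, nll = total / n_inst,
                                           dev_f = dev_f))
      if (verbose) {
        message(sprintf("epoch %d: mean nll %.4f%s", epoch, total / n_inst,
                        if (is.na(dev_f)) "" else sprintf(", dev F %.4f", dev_f)))
      }
    }
  })
  if (is.null(dev_docs)) best <- list(f = NA_real_, params = params,
                                      epoch = config$epochs)
  new_mcnn(best$params, config, vocab, lexicon, history, best$epoch)
}

new_mcnn <- function(params, config, vocab, lexicon, history, best_epoch) {
  structure(list(params = params, config = config, vocab = vocab,
                 lexicon = lexicon, history = history,
                 best_epoch = best_epoch),
            class = "mcnn")
}

#' @export
print.mcnn <- function(x, ...) {
  cfg <- x$config
  cat("Multiple-label convolutional BIO tagger\n")
  cat(sprintf("  window %d, embeddings %d+%s+%s, %d conv layer(s) x %d filters\n",
              cfg$window, cfg$word_dim,
              if (cfg$use_char) cfg$char_cnn_filters else "0(char off)",
              if (cfg$use_lexicon) cfg$lex_dim else "0(lexicon off)",
              cfg$n_conv_layers, cfg$conv_filters))
  cat(sprintf("  MLS %s (%s), dropout %.2f, vocab %d words / %d chars\n",
              if (cfg$mls) "on" else "off", cfg$aux_mode, cfg$dropout,
              length(x$vocab$words) - 2L, length(x$vocab$chars) - 2L))
  if (!is.null(x$history) && nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s), final mean nll %.4f", last$epoch,
                last$nll))
    if (!is.na(last$dev_f)) {
      cat(sprintf(", best dev F %.4f (epoch %d)",
                  max(x$history$dev_f, na.rm = TRUE), x$best_epoch))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.mcnn <- function(object, ...) {
  n_par <- sum(vapply(rapply(object$params, identity, how = "unlist"),
                      length, integer(1)))
  out <- list(config = object$config, n_parameters = n_par,
              history = object$history, best_epoch = object$best_epoch)
  class(out) <- "summary.mcnn"
  out
}

#' @export
print.summary.mcnn <- function(x, ...) {
  cat(sprintf("mcnn model: %d learnable parameters, best epoch %d\n",
              x$n_parameters, x$best_epoch))
  if (!is.null(x$history)) print(x$history, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mcnn <- function(object, ...) object$params

#' Plot the training history
#'
#' Mean per-instance negative log-likelihood by epoch, with development-set
#' mention F overlaid when it was tracked during fitting.
#' @param x A fitted `mcnn` model.
#' @param ... Passed to [plot()].
#' @export
plot.mcnn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0L) stop("no training history to plot")
  graphics::plot(h$epoch, h$nll, type = "b", xlab = "epoch",
                 ylab = "mean -log likelihood", ...)
  if (any(!is.na(h$dev_f))) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(h$epoch, h$dev_f, type = "b", col = "red", axes = FALSE,
                   xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("dev mention F", side = 4, line = 2, col = "red")
  }
  invisible(x)
}

#' Predict BIO labels or disease mentions
#'
#' Tags every token with the argmax of the main softmax head (ties broken
#' toward `O`, then `B`); the auxiliary MLS head is discarded at inference.
#' With `type = "mentions"`, ill-legal BIO sequences are repaired, label runs
#' are converted to character spans, and (by default) abbreviation
#' propagation adds short-form occurrences of recognized long forms.
#'
#' @param object A fitted `mcnn` model.
#' @param newdata A list of documents, or of `list(tokens, labels)` /
#'   token-data.frame sentences (labels ignored).
#' @param type `"mentions"` (documents only), `"labels"`, or `"prob"`.
#' @param postprocess Repair ill-legal sequences before decoding mentions.
#' @param strict_bb In repair, also treat `B,B` as ill-legal.
#' @param abbrev Apply abbreviation propagation (documents only).
#' @param ... Unused.
#' @return For `"mentions"`: a mention data.frame (`doc_id`, `start`, `end`,
#'   `text`, `type`). For `"labels"`: a list of character label vectors. For
#'   `"prob"`: a list of n x 3 probability matrices.
#' @export
predict.mcnn <- function(object, newdata, type = c("mentions", "labels", "prob"),
                         postprocess = TRUE, strict_bb = FALSE, abbrev = TRUE,
                         ...) {
  type <- match.arg(type)
  cfg <- object$config
  first <- if (length(newdata) > 0L) newdata[[1]] else NULL
  is_docs <- !is.null(first) && !is.data.frame(first) &&
    is.null(first$tokens) &&
    (!is.null(first$doc_id) || !is.null(first$sentences))
  if (type == "mentions" && !is_docs) {
    stop("type = 'mentions' needs documents (with character offsets)")
  }
  if (is_docs) {
    newdata <- lapply(newdata, function(d) {
      if (is.null(d$sentences)) preprocess_document(d) else d
    })
    sents <- unlist(lapply(newdata, function(d) {
      lapply(d$sentences, function(t) list(tokens = t, labels = NULL))
    }), recursive = FALSE)
    doc_of <- rep(seq_along(newdata),
                  vapply(newdata, function(d) length(d$sentences), integer(1)))
  } else {
    sents <- lapply(newdata, function(s) {
      if (!is.null(s$tokens)) list(tokens = s$tokens, labels = NULL)
      else list(tokens = s, labels = NULL)
    })
    doc_of <- NULL
  }
  keep <- vapply(sents, function(s) nrow(s$tokens) > 0L, logical(1))
  labels <- vector("list", length(sents))
  probs <- vector("list", length(sents))
  if (any(keep)) {
    enc <- encode_corpus(sents[keep], object$vocab, lexicon = object$lexicon,
                         window = cfg$window)
    pm <- matrix(0, enc$n, 3L)
    for (b0 in seq(1L, enc$n, by = 1024L)) {
      rows <- b0:min(b0 + 1023L, enc$n)
      fwd <- nn_forward(object$params, batch_rows(enc, rows), cfg,
                        train = FALSE)
      pm[rows, ] <- exp(log_softmax(fwd$Sm))
    }
    # argmax with tie preference O > B > I
    pref <- c(label_id("O"), label_id("B"), label_id("I"))
    lab_id <- apply(pm, 1L, function(p) pref[which.max(p[pref])])
    ki <- which(keep)
    for (j in seq_along(ki)) {
      rows <- which(enc$sentence == j)
      labels[[ki[j]]] <- BIO_LABELS[lab_id[rows]]
      probs[[ki[j]]] <- pm[rows, , drop = FALSE]
    }
  }
  for (j in which(!keep)) {
    labels[[j]] <- character(0)
    probs[[j]] <- matrix(0, 0L, 3L)
  }
  if (type == "prob") return(probs)
  if (postprocess) {
    labels <- lapply(labels, function(l) repair_illegal(l, strict_bb)$labels)
  }
  if (type == "labels") return(labels)
  # mentions
  out <- empty_mentions()
  for (di in seq_along(newdata)) {
    d <- newdata[[di]]
    idx <- which(doc_of == di)
    men <- empty_mentions()
    for (j in idx) {
      lab <- labels[[j]]
      if (!postprocess) lab <- repair_illegal(lab)$labels
      men <- rbind(men, bio_to_mentions(sents[[j]]$tokens, lab,
                                        doc_id = d$doc_id, text = d$text))
    }
    if (abbrev) {
      pairs <- extract_abbreviations(d)
      men <- propagate_abbreviations(d, men, pairs)
    }
    out <- rbind(out, men)
  }
  out
}

#' Log-likelihood of labelled data under a fitted model
#'
#' Computes `J(theta)`: the summed log-probability of the main labels plus,
#' when MLS is on, of the auxiliary (previous, next) label pairs.
#'
#' @param object A fitted `mcnn` model.
#' @param newdata Documents or labelled sentences; defaults to an error
#'   (training data are not stored).
#' @param ... Unused.
#' @return An object of class `logLik` (attribute `nobs` = token count).
#' @export
logLik.mcnn <- function(object, newdata, ...) {
  sents <- as_labelled_sentences(newdata)
  enc <- encode_corpus(sents, object$vocab, lexicon = object$lexicon,
                       window = object$config$window)
  total <- 0
  for (b0 in seq(1L, enc$n, by = 1024L)) {
    rows <- b0:min(b0 + 1023L, enc$n)
    batch <- batch_rows(enc, rows)
    fwd <- nn_forward(object$params, batch, object$config, train = FALSE)
    total <- total - nn_nll(fwd, batch, object$config)
  }
  structure(total, nobs = enc$n, df = NA_integer_, class = "logLik")
}

#' Finite-difference check of the analytic gradients
#'
#' Builds a tiny randomly initialized model and batch (window 5, 2 filters,
#' small embeddings), computes the analytic gradient of the summed negative
#' log-likelihood, and compares every coordinate against central finite
#' differences.
#'
#' @param config Optional small [mcnn_config()]; defaults to a tiny one.
#' @param n_instances Number of synthetic instances in the batch.
#' @param eps Finite-difference step.
#' @param seed Seed for parameters and batch.
#' @return Max relative error across all parameters (invisibly also per-block,
#'   as attribute `"blocks"`).
#' @export
mcnn_gradient_check <- function(config = NULL, n_instances = 4L, eps = 1e-5,
                                seed = 1L) {
  if (is.null(config)) {
    config <- mcnn_config(window = 5L, word_dim = 4L, char_dim = 3L,
                          lex_dim = 2L, char_cnn_window = 3L,
                          char_cnn_filters = 2L, conv_window = 3L,
                          conv_filters = 2L, n_conv_layers = 2L,
                          dropout = 0, seed = seed)
  }
  stopifnot(config$dropout == 0)   # dropout makes the loss stochastic
  vocab <- structure(list(words = c("<pad>", "<unk>", letters[1:6]),
                          chars = c("<pad>", "<unk>", letters[1:8])),
                     class = "mcnn_vocab")
  batch <- with_seed(seed, {
    n <- n_instances; w <- config$window
    forms <- c(list(rep(PAD_ID, 3L)),
               lapply(1:6, function(i) sample(seq_along(vocab$chars), 4L,
                                              replace = TRUE)))
    list(W = matrix(sample(seq_along(vocab$words), n * w, TRUE), n, w),
         Fm = matrix(sample(seq_along(forms), n * w, TRUE), n, w),
         L = matrix(sample(1:3, n * w, TRUE), n, w),
         forms = forms,
         y = sample(1:3, n, TRUE),
         y_prev = sample(1:3, n, TRUE),
         y_next = sample(1:3, n, TRUE),
         n = n, window = w)
  })
  params <- nn_init_params(config, vocab)
  # randomize the (normally zero) biases: exact-zero pre-activations put a
  # ReLU kink right at the evaluation point, where finite differences and
  # the (one-sided) analytic derivative legitimately disagree
  params <- with_seed(seed + 1L, {
    jitter <- function(v) v + stats::runif(length(v), -0.2, 0.2)
    if (!is.null(params$bc)) params$bc <- jitter(params$bc)
    for (l in seq_along(params$conv)) {
      params$conv[[l]]$b <- jitter(params$conv[[l]]$b)
    }
    params$bm <- jitter(params$bm)
    if (!is.null(params$ba)) params$ba <- jitter(params$ba)
    params
  })
  ana <- nn_loss_grad(params, batch, config, train = FALSE)

  # densify sparse embedding gradients
  dense <- function(spec, template) {
    G <- matrix(0, nrow(template), ncol(template))
    G[spec$ids, ] <- spec$g
    G
  }
  agrads <- ana$grads
  agrads$Ew <- dense(agrads$Ew, params$Ew)
  if (!is.null(agrads$Ec)) agrads$Ec <- dense(agrads$Ec, params$Ec)
  if (!is.null(agrads$El)) agrads$El <- dense(agrads$El, params$El)

  loss_at <- function(p) nn_loss_grad(p, batch, config, train = FALSE,
                                      want_grad = FALSE)$loss
  max_rel <- 0
  blocks <- c()
  check_block <- function(getter, setter, aG, label) {
    vals <- getter(params)
    num <- vals
    for (i in seq_along(vals)) {
      v <- vals
      v[i] <- vals[i] + eps
      up <- loss_at(setter(params, v))
      v[i] <- vals[i] - eps
      dn <- loss_at(setter(params, v))
      num[i] <- (up - dn) / (2 * eps)
    }
    rel <- abs(num - aG) / pmax(abs(num), abs(aG), 1e-4)
    blocks[label] <<- max(rel)
    max_rel <<- max(max_rel, max(rel))
  }
  check_block(function(p) p$Ew, function(p, v) { p$Ew[] <- v; p },
              agrads$Ew, "Ew")
  if (config$use_char) {
    check_block(function(p) p$Ec, function(p, v) { p$Ec[] <- v; p },
                agrads$Ec, "Ec")
    check_block(function(p) p$Wc, function(p, v) { p$Wc[] <- v; p },
                agrads$Wc, "Wc")
    check_block(function(p) p$bc, function(p, v) { p$bc[] <- v; p },
                agrads$bc, "bc")
  }
  if (config$use_lexicon) {
    check_block(function(p) p$El, function(p, v) { p$El[] <- v; p },
                agrads$El, "El")
  }
  for (l in seq_len(config$n_conv_layers)) {
    local({
      ll <- l
      check_block(function(p) p$conv[[ll]]$W,
                  function(p, v) { p$conv[[ll]]$W[] <- v; p },
                  agrads$conv[[ll]]$W, paste0("convW", ll))
      check_block(function(p) p$conv[[ll]]$b,
                  function(p, v) { p$conv[[ll]]$b[] <- v; p },
                  agrads$conv[[ll]]$b, paste0("convb", ll))
    })
  }
  check_block(function(p) p$Wm, function(p, v) { p$Wm[] <- v; p },
              agrads$Wm, "Wm")
  check_block(function(p) p$bm, function(p, v) { p$bm[] <- v; p },
              agrads$bm, "bm")
  if (config$mls) {
    check_block(function(p) p$Wa, function(p, v) { p$Wa[] <- v; p },
                agrads$Wa, "Wa")
    check_block(function(p) p$ba, function(p, v) { p$ba[] <- v; p },
                agrads$ba, "ba")
  }
  structure(max_rel, blocks = blocks)
}
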