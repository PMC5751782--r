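# Network internals: parameter initialization, the batched forward pass
# (character CNN -> embedding concatenation -> stacked pooling-free
# convolutions -> flatten -> main/auxiliary output heads), the analytic
# backward pass, and the SGD update. Everything operates on position-major
# block matrices: a tensor [n instances, P positions, D dims] is stored as a
# (n*P) x D matrix whose rows ((p-1)*n + 1) .. (p*n) hold position p.

blk <- function(M, p, n) M[((p - 1L) * n + 1L):(p * n), , drop = FALSE]

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

token_dim <- function(config) {
  config$word_dim +
    (if (config$use_char) config$char_cnn_filters else 0L) +
    (if (config$use_lexicon) config$lex_dim else 0L)
}

flat_dim <- function(config) {
  p_last <- config$window - config$n_conv_layers * (config$conv_window - 1L)
  p_last * config$conv_filters
}

aux_dim <- function(config) if (config$aux_mode == "joint") 9L else 6L

# Initialize all learnable parameters under config$seed. Word embeddings may
# be supplied (pre-trained table); otherwise uniform in +-0.05.
nn_init_params <- function(config, vocab, word_table = NULL) {
  with_seed(config$seed, {
    p <- list()
    p$Ew <- if (is.null(word_table)) {
      matrix(stats::runif(length(vocab$words) * config$word_dim, -0.05, 0.05),
             nrow = length(vocab$words))
    } else word_table
    if (config$use_char) {
      p$Ec <- matrix(stats::runif(length(vocab$chars) * config$char_dim,
                                  -0.05, 0.05), nrow = length(vocab$chars))
      p$Wc <- glorot(config$char_cnn_window * config$char_dim,
                     config$char_cnn_filters)
      p$bc <- numeric(config$char_cnn_filters)
    }
    if (config$use_lexicon) {
      p$El <- matrix(stats::runif(3L * config$lex_dim, -0.05, 0.05), nrow = 3L)
    }
    d_in <- token_dim(config)
    p$conv <- vector("list", config$n_conv_layers)
    for (l in seq_len(config$n_conv_layers)) {
      p$conv[[l]] <- list(
        W = glorot(config$conv_window * d_in, config$conv_filters),
        b = numeric(config$conv_filters))
      d_in <- config$conv_filters
    }
    fd <- flat_dim(config)
    p$Wm <- glorot(fd, 3L)
    p$bm <- numeric(3L)
    if (config$mls) {
      p$Wa <- glorot(fd, aux_dim(config))
      p$ba <- numeric(aux_dim(config))
    }
    p
  })
}

# Row-wise log-softmax with max subtraction for numerical stability.
log_softmax <- function(S) {
  if (any(!is.finite(S))) stop("non-finite scores in softmax")
  m <- apply(S, 1L, max)
  Z <- S - m
  Z - log(rowSums(exp(Z)))
}

#' Softmax label probabilities from output-layer confidence scores
#'
#' Converts the raw confidence scores of the main (and optionally auxiliary)
#' output head into probability distributions via a numerically stable
#' softmax (max-subtraction). Each returned distribution is non-negative and
#' sums to 1; the operation is invariant to adding a constant to all scores.
#'
#' @param out_main Numeric vector of main-head scores (length 3 for B/I/O),
#'   or a matrix with one row per instance.
#' @param out_aux Optional auxiliary-head scores (vector or matrix).
#' @return List with `p_main` (and `p_aux` when given), same shape as input.
#' @examples
#' label_probs(c(log(2), 0, 0))$p_main   # 0.5 0.25 0.25
#' @export
label_probs <- function(out_main, out_aux = NULL) {
  one <- function(S) {
    vec <- is.null(dim(S))
    if (vec) S <- matrix(S, nrow = 1L)
    P <- exp(log_softmax(S))
    if (vec) drop(P) else P
  }
  out <- list(p_main = one(out_main))
  if (!is.null(out_aux)) out$p_aux <- one(out_aux)
  out
}

# Take a subset of instance rows from an encoded corpus.
batch_rows <- function(enc, rows) {
  list(W = enc$W[rows, , drop = FALSE],
       Fm = enc$Fm[rows, , drop = FALSE],
       L = enc$L[rows, , drop = FALSE],
       forms = enc$forms,
       y = enc$y[rows],
       y_prev = enc$y_prev[rows],
       y_next = enc$y_next[rows],
       n = length(rows),
       window = enc$window)
}

# Full forward pass over a batch. Returns scores plus every intermediate
# needed for the backward pass. Dropout (inverted) is applied only when
# train = TRUE, using the current RNG stream.
nn_forward <- function(params, batch, config, train = FALSE) {
  n <- batch$n
  w <- batch$window
  cache <- list(n = n, w = w)

  # --- character-level CNN over the unique word forms of the batch ---
  if (config$use_char) {
    uf <- sort(unique(as.vector(batch$Fm)))
    fmap <- matrix(match(batch$Fm, uf), nrow = n)
    seqs <- batch$forms[uf]
    lens <- lengths(seqs)
    Lmax <- max(lens)
    U <- length(uf)
    Cmat <- matrix(PAD_ID, U, Lmax)
    for (u in seq_len(U)) Cmat[u, seq_len(lens[u])] <- seqs[[u]]
    Xc <- params$Ec[as.vector(Cmat), , drop = FALSE]     # (U*Lmax) x char_dim
    if (train && config$dropout > 0) {
      mask_c <- matrix(stats::rbinom(length(Xc), 1L, 1 - config$dropout) /
                         (1 - config$dropout), nrow = nrow(Xc))
      Xc <- Xc * mask_c
      cache$mask_c <- mask_c
    }
    ccw <- config$char_cnn_window
    Pc <- Lmax - ccw + 1L
    Fc <- config$char_cnn_filters
    Zc <- matrix(0, U * Pc, Fc)
    for (p in seq_len(Pc)) {
      inp <- do.call(cbind, lapply(seq_len(ccw) - 1L,
                                   function(o) blk(Xc, p + o, U)))
      Zc[((p - 1L) * U + 1L):(p * U), ] <- inp %*% params$Wc +
        rep(params$bc, each = U)
    }
    # max over positions, remembering the argmax for backprop
    Crepr <- blk(Zc, 1L, U)
    Amax <- matrix(1L, U, Fc)
    if (Pc > 1L) {
      for (p in 2L:Pc) {
        cand <- blk(Zc, p, U)
        upd <- cand > Crepr
        Crepr[upd] <- cand[upd]
        Amax[upd] <- p
      }
    }
    cache$char <- list(uf = uf, fmap = fmap, Cmat = Cmat, Xc = Xc, Zc = Zc,
                       Amax = Amax, U = U, Pc = Pc, Lmax = Lmax)
  }

  # --- per-token feature vectors: word (+ char repr) (+ lexicon) ---
  parts <- list(params$Ew[as.vector(batch$W), , drop = FALSE])
  if (config$use_char) {
    parts[[length(parts) + 1L]] <- cache$char$Crepr <-
      Crepr[as.vector(cache$char$fmap), , drop = FALSE]
  }
  if (config$use_lexicon) {
    parts[[length(parts) + 1L]] <- params$El[as.vector(batch$L), , drop = FALSE]
  }
  Tmat <- do.call(cbind, parts)                          # (n*w) x token_dim
  if (train && config$dropout > 0) {
    mask_t <- matrix(stats::rbinom(length(Tmat), 1L, 1 - config$dropout) /
                       (1 - config$dropout), nrow = nrow(Tmat))
    Tmat <- Tmat * mask_t
    cache$mask_t <- mask_t
  }

  # --- stacked pooling-free convolutions with ReLU ---
  cw <- config$conv_window
  H <- Tmat
  P_in <- w
  cache$H <- list(Tmat)          # inputs to each layer
  cache$S <- list()              # pre-activations of each layer
  for (l in seq_len(config$n_conv_layers)) {
    P_out <- P_in - (cw - 1L)
    D_out <- config$conv_filters
    S <- matrix(0, n * P_out, D_out)
    for (p in seq_len(P_out)) {
      inp <- do.call(cbind, lapply(seq_len(cw) - 1L,
                                   function(o) blk(H, p + o, n)))
      S[((p - 1L) * n + 1L):(p * n), ] <- inp %*% params$conv[[l]]$W +
        rep(params$conv[[l]]$b, each = n)
    }
    H <- S * (S > 0)
    cache$S[[l]] <- S
    cache$H[[l + 1L]] <- H
    P_in <- P_out
  }

  # --- flatten + output heads ---
  Flat <- matrix(0, n, P_in * config$conv_filters)
  for (p in seq_len(P_in)) {
    Flat[, ((p - 1L) * config$conv_filters + 1L):(p * config$conv_filters)] <-
      blk(H, p, n)
  }
  cache$Flat <- Flat
  cache$P_last <- P_in
  out <- list(Sm = Flat %*% params$Wm + rep(params$bm, each = n))
  if (config$mls) out$Sa <- Flat %*% params$Wa + rep(params$ba, each = n)
  out$cache <- cache
  out
}

# Negative log-likelihood of a forward result against batch targets:
# -J = -sum_i log p_main(y_i) - sum_i log p_aux(yaux_i)     (when MLS is on)
nn_nll <- function(fwd, batch, config) {
  n <- batch$n
  lp_m <- log_softmax(fwd$Sm)
  nll <- -sum(lp_m[cbind(seq_len(n), batch$y)])
  if (config$mls) {
    if (config$aux_mode == "joint") {
      lp_a <- log_softmax(fwd$Sa)
      tgt <- aux_joint_id(batch$y_prev, batch$y_next)
      nll <- nll - sum(lp_a[cbind(seq_len(n), tgt)])
    } else {
      lp_p <- log_softmax(fwd$Sa[, 1:3, drop = FALSE])
      lp_n <- log_softmax(fwd$Sa[, 4:6, drop = FALSE])
      nll <- nll - sum(lp_p[cbind(seq_len(n), batch$y_prev)]) -
        sum(lp_n[cbind(seq_len(n), batch$y_next)])
    }
  }
  nll
}

# Loss (-J, summed over the batch) and analytic gradients of every parameter.
# Embedding gradients are sparse: list(ids, g) with one row of g per touched
# table row. train toggles dropout; gradients flow through the same masks.
nn_loss_grad <- function(params, batch, config, train = FALSE,
                         want_grad = TRUE) {
  n <- batch$n
  fwd <- nn_forward(params, batch, config, train = train)
  loss <- nn_nll(fwd, batch, config)
  if (!want_grad) return(list(loss = loss, n = n))
  cache <- fwd$cache
  g <- list()

  # output heads: d(-J)/dS = softmax(S) - onehot(target)
  Pm <- exp(log_softmax(fwd$Sm))
  dSm <- Pm
  dSm[cbind(seq_len(n), batch$y)] <- dSm[cbind(seq_len(n), batch$y)] - 1
  g$Wm <- crossprod(cache$Flat, dSm)
  g$bm <- colSums(dSm)
  dFlat <- dSm %*% t(params$Wm)
  if (config$mls) {
    if (config$aux_mode == "joint") {
      Pa <- exp(log_softmax(fwd$Sa))
      dSa <- Pa
      tgt <- aux_joint_id(batch$y_prev, batch$y_next)
      dSa[cbind(seq_len(n), tgt)] <- dSa[cbind(seq_len(n), tgt)] - 1
    } else {
      Pp <- exp(log_softmax(fwd$Sa[, 1:3, drop = FALSE]))
      Pn <- exp(log_softmax(fwd$Sa[, 4:6, drop = FALSE]))
      Pp[cbind(seq_len(n), batch$y_prev)] <-
        Pp[cbind(seq_len(n), batch$y_prev)] - 1
      Pn[cbind(seq_len(n), batch$y_next)] <-
        Pn[cbind(seq_len(n), batch$y_next)] - 1
      dSa <- cbind(Pp, Pn)
    }
    g$Wa <- crossprod(cache$Flat, dSa)
    g$ba <- colSums(dSa)
    dFlat <- dFlat + dSa %*% t(params$Wa)
  }

  # un-flatten
  Fd <- config$conv_filters
  dH <- matrix(0, n * cache$P_last, Fd)
  for (p in seq_len(cache$P_last)) {
    dH[((p - 1L) * n + 1L):(p * n), ] <-
      dFlat[, ((p - 1L) * Fd + 1L):(p * Fd), drop = FALSE]
  }

  # backward through the convolution stack
  cw <- config$conv_window
  g$conv <- vector("list", config$n_conv_layers)
  for (l in rev(seq_len(config$n_conv_layers))) {
    S <- cache$S[[l]]
    Hin <- cache$H[[l]]
    D_in <- ncol(Hin)
    P_out <- nrow(S) / n
    dS <- dH * (S > 0)
    gW <- matrix(0, cw * D_in, Fd)
    gb <- numeric(Fd)
    dHin <- matrix(0, nrow(Hin), D_in)
    for (p in seq_len(P_out)) {
      dS_p <- blk(dS, p, n)
      inp <- do.call(cbind, lapply(seq_len(cw) - 1L,
                                   function(o) blk(Hin, p + o, n)))
      gW <- gW + crossprod(inp, dS_p)
      gb <- gb + colSums(dS_p)
      dInp <- dS_p %*% t(params$conv[[l]]$W)
      for (o in seq_len(cw) - 1L) {
        rows <- ((p + o - 1L) * n + 1L):((p + o) * n)
        dHin[rows, ] <- dHin[rows, ] +
          dInp[, (o * D_in + 1L):((o + 1L) * D_in), drop = FALSE]
      }
    }
    g$conv[[l]] <- list(W = gW, b = gb)
    dH <- dHin
  }

  # dH is now the gradient w.r.t. the (dropped-out) token matrix
  dT <- dH
  if (!is.null(cache$mask_t)) dT <- dT * cache$mask_t
  wd <- config$word_dim
  dWord <- dT[, seq_len(wd), drop = FALSE]
  off <- wd
  gw_tab <- rowsum(dWord, group = as.vector(batch$W))
  g$Ew <- list(ids = as.integer(rownames(gw_tab)), g = unname(gw_tab))

  if (config$use_char) {
    Fc <- config$char_cnn_filters
    dChar <- dT[, (off + 1L):(off + Fc), drop = FALSE]
    off <- off + Fc
    ch <- cache$char
    # sum over all window positions sharing each unique form; rowsum sorts
    # groups numerically and every id 1..U occurs, so row u is form u
    dCrepr <- unname(rowsum(dChar, group = as.vector(ch$fmap)))
    U <- ch$U; Pc <- ch$Pc
    dZc <- matrix(0, U * Pc, Fc)
    rows <- as.vector((ch$Amax - 1L) * U + seq_len(U))
    cols <- rep(seq_len(Fc), each = U)
    dZc[cbind(rows, cols)] <- as.vector(dCrepr)
    ccw <- config$char_cnn_window
    cd <- config$char_dim
    gWc <- matrix(0, ccw * cd, Fc)
    gbc <- numeric(Fc)
    dXc <- matrix(0, nrow(ch$Xc), cd)
    for (p in seq_len(Pc)) {
      dZ_p <- blk(dZc, p, U)
      inp <- do.call(cbind, lapply(seq_len(ccw) - 1L,
                                   function(o) blk(ch$Xc, p + o, U)))
      gWc <- gWc + crossprod(inp, dZ_p)
      gbc <- gbc + colSums(dZ_p)
      dInp <- dZ_p %*% t(params$Wc)
      for (o in seq_len(ccw) - 1L) {
        rows2 <- ((p + o - 1L) * U + 1L):((p + o) * U)
        dXc[rows2, ] <- dXc[rows2, ] +
          dInp[, (o * cd + 1L):((o + 1L) * cd), drop = FALSE]
      }
    }
    g$Wc <- gWc
    g$bc <- gbc
    if (!is.null(cache$mask_c)) dXc <- dXc * cache$mask_c
    gc_tab <- rowsum(dXc, group = as.vector(ch$Cmat))
    g$Ec <- list(ids = as.integer(rownames(gc_tab)), g = unname(gc_tab))
  }

  if (config$use_lexicon) {
    dLex <- dT[, (off + 1L):(off + config$lex_dim), drop = FALSE]
    gl_tab <- rowsum(dLex, group = as.vector(batch$L))
    g$El <- list(ids = as.integer(rownames(gl_tab)), g = unname(gl_tab))
  }

  list(loss = loss, n = n, grads = g)
}

# In-place-style SGD step on mean gradients (grads are sums over the batch).
nn_sgd_step <- function(params, grads, lr, n) {
  s <- lr / n
  params$Ew[grads$Ew$ids, ] <- params$Ew[grads$Ew$ids, ] - s * grads$Ew$g
  if (!is.null(grads$Ec)) {
    params$Ec[grads$Ec$ids, ] <- params$Ec[grads$Ec$ids, ] - s * grads$Ec$g
    params$Wc <- params$Wc - s * grads$Wc
    params$bc <- params$bc - s * grads$bc
  }
  if (!is.null(grads$El)) {
    params$El[grads$El$ids, ] <- params$El[grads$El$ids, ] - s * grads$El$g
  }
  for (l in seq_along(params$conv)) {
    params$conv[[l]]$W <- params$conv[[l]]$W - s * grads$conv[[l]]$W
    params$conv[[l]]$b <- params$conv[[l]]$b - s * grads$conv[[l]]$b
  }
  params$Wm <- params$Wm - s * grads$Wm
  params$bm <- params$bm - s * grads$bm
  if (!is.null(grads$Wa)) {
    params$Wa <- params$Wa - s * grads$Wa
    params$ba <- params$ba - s * grads$ba
  }
  params
}
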