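# Decoder-only transformer in base R. Pre-norm residual blocks, learned
# absolute positional embeddings, causal multi-head attention, GELU
# feed-forward, output head tied to the token embedding. Heavy lifting is
# BLAS matrix multiplication; sequences in a minibatch are concatenated
# row-wise (never padded), with attention computed per sequence so the
# causal mask never crosses sequence boundaries.

LN_EPS <- 1e-5

# ---- parameter tree -------------------------------------------------------

.init_params <- function(cfg) {
  d <- cfg$d_model; dff <- cfg$d_ff
  rmat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(ln1_g = rep(1, d), ln1_b = rep(0, d),
         Wq = rmat(d, d), bq = rep(0, d),
         Wk = rmat(d, d), bk = rep(0, d),
         Wv = rmat(d, d), bv = rep(0, d),
         Wo = rmat(d, d, sd = 0.02 / sqrt(2 * cfg$n_layers)), bo = rep(0, d),
         ln2_g = rep(1, d), ln2_b = rep(0, d),
         W1 = rmat(d, dff), b1 = rep(0, dff),
         W2 = rmat(dff, d, sd = 0.02 / sqrt(2 * cfg$n_layers)), b2 = rep(0, d))
  })
  params <- list(We = rmat(cfg$vocab_size, d),
                 Wp = rmat(cfg$context_len, d, sd = 0.01),
                 layers = layers,
                 lnf_g = rep(1, d), lnf_b = rep(0, d))
  # self-consistency: the instantiated tensors must realize the closed form
  n_inst <- .tree_size(params)
  n_formula <- count_parameters(cfg)
  if (n_inst != n_formula)
    stop("internal error: instantiated parameter count ", n_inst,
         " != count_parameters() = ", n_formula)
  params
}

.tree_size <- function(x) {
  if (is.list(x)) sum(vapply(x, .tree_size, numeric(1))) else length(x)
}

.tree_map <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1L]])) {
    out <- lapply(seq_along(xs[[1L]]), function(i) {
      do.call(.tree_map, c(list(f), lapply(xs, `[[`, i)))
    })
    names(out) <- names(xs[[1L]])
    out
  } else {
    do.call(f, xs)
  }
}

.tree_sumsq <- function(x) {
  if (is.list(x)) sum(vapply(x, .tree_sumsq, numeric(1))) else sum(x * x)
}

# ---- primitive layers -----------------------------------------------------

.ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

.gelu <- function(x) x * pnorm(x)
.gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

.softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# ---- forward / backward over a concatenated minibatch ---------------------

# seqs: list of 0-based id vectors. Returns loss, caches (if backward = TRUE
# they are retained), logits at requested rows.
.fwd_batch <- function(params, cfg, seqs, keep_cache = FALSE,
                       dropout = 0, logits_rows = NULL) {
  lens <- lengths(seqs)
  if (any(lens > cfg$context_len))
    stop("sequence of length ", max(lens), " exceeds context window ",
         cfg$context_len)
  ids <- unlist(seqs, use.names = FALSE)
  N <- length(ids)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  scl <- 1 / sqrt(dh)

  drop_mask <- function() {
    if (dropout > 0) {
      matrix(rbinom(N * d, 1L, 1 - dropout), N, d) / (1 - dropout)
    } else NULL
  }
  apply_mask <- function(X, m) if (is.null(m)) X else X * m

  X <- params$We[ids + 1L, , drop = FALSE] + params$Wp[pos, , drop = FALSE]
  m_emb <- drop_mask()
  X <- apply_mask(X, m_emb)

  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    L <- params$layers[[l]]
    ln1 <- .ln_fwd(X, L$ln1_g, L$ln1_b)
    A1 <- ln1$y
    Q <- sweep(A1 %*% L$Wq, 2L, L$bq, "+")
    K <- sweep(A1 %*% L$Wk, 2L, L$bk, "+")
    V <- sweep(A1 %*% L$Wv, 2L, L$bv, "+")
    O <- matrix(0, N, d)
    for (s in seq_along(seqs)) {
      r <- starts[s]:(starts[s] + lens[s] - 1L)
      for (h in seq_len(nh)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[r, hc, drop = FALSE], K[r, hc, drop = FALSE]) * scl
        S[upper.tri(S)] <- -Inf
        P <- .softmax_rows(S)
        O[r, hc] <- P %*% V[r, hc, drop = FALSE]
      }
    }
    Attn <- sweep(O %*% L$Wo, 2L, L$bo, "+")
    m_att <- drop_mask()
    X1 <- X + apply_mask(Attn, m_att)
    ln2 <- .ln_fwd(X1, L$ln2_g, L$ln2_b)
    A2 <- ln2$y
    H1pre <- sweep(A2 %*% L$W1, 2L, L$b1, "+")
    H1 <- .gelu(H1pre)
    F2 <- sweep(H1 %*% L$W2, 2L, L$b2, "+")
    m_ff <- drop_mask()
    X2 <- X1 + apply_mask(F2, m_ff)
    if (keep_cache) {
      caches[[l]] <- list(X_in = X, ln1 = ln1, A1 = A1, Q = Q, K = K, V = V,
                          O = O, X1 = X1, ln2 = ln2, A2 = A2,
                          H1pre = H1pre, H1 = H1,
                          m_att = m_att, m_ff = m_ff)
    }
    X <- X2
  }
  lnf <- .ln_fwd(X, params$lnf_g, params$lnf_b)
  H <- lnf$y

  # next-token targets: every row except the last of each sequence
  pred_rows <- setdiff(seq_len(N), starts + lens - 1L)
  targets <- ids[pred_rows + 1L]
  keep <- targets != 0L & ids[pred_rows] != 0L  # mask PAD if it ever appears
  pred_rows <- pred_rows[keep]
  targets <- targets[keep]

  logits <- H[pred_rows, , drop = FALSE] %*% t(params$We)
  if (nrow(logits)) {
    mx <- logits[cbind(seq_len(nrow(logits)),
                       max.col(logits, ties.method = "first"))]
    logZ <- mx + log(rowSums(exp(logits - mx)))
    logp <- logits[cbind(seq_along(targets), targets + 1L)] - logZ
    loss <- -mean(logp)
  } else {
    logZ <- numeric(0)
    loss <- NA_real_
  }

  extra_logits <- if (!is.null(logits_rows)) {
    H[logits_rows, , drop = FALSE] %*% t(params$We)
  } else NULL

  list(loss = loss, H = H, lnf = lnf, caches = caches,
       ids = ids, pos = pos, N = N, starts = starts, lens = lens,
       pred_rows = pred_rows, targets = targets,
       logits = logits, logZ = logZ, m_emb = m_emb,
       extra_logits = extra_logits)
}

.bwd_batch <- function(params, cfg, fw) {
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  scl <- 1 / sqrt(dh)
  N <- fw$N
  npred <- length(fw$pred_rows)

  Pmat <- exp(fw$logits - fw$logZ)
  Pmat[cbind(seq_len(npred), fw$targets + 1L)] <-
    Pmat[cbind(seq_len(npred), fw$targets + 1L)] - 1
  dlogits <- Pmat / npred

  dWe <- matrix(0, cfg$vocab_size, d)
  dWe <- dWe + crossprod(dlogits, fw$H[fw$pred_rows, , drop = FALSE])
  dH <- matrix(0, N, d)
  dH[fw$pred_rows, ] <- dlogits %*% params$We

  bl <- .ln_bwd(dH, fw$lnf, params$lnf_g)
  dX <- bl$dX
  grads <- list(We = dWe, Wp = NULL, layers = vector("list", cfg$n_layers),
                lnf_g = bl$dg, lnf_b = bl$db)

  apply_mask <- function(X, m) if (is.null(m)) X else X * m

  for (l in rev(seq_len(cfg$n_layers))) {
    L <- params$layers[[l]]
    cc <- fw$caches[[l]]
    # feed-forward branch
    dF2 <- apply_mask(dX, cc$m_ff)
    dH1 <- dF2 %*% t(L$W2)
    dW2 <- crossprod(cc$H1, dF2)
    db2 <- colSums(dF2)
    dH1pre <- dH1 * .gelu_grad(cc$H1pre)
    dA2 <- dH1pre %*% t(L$W1)
    dW1 <- crossprod(cc$A2, dH1pre)
    db1 <- colSums(dH1pre)
    b2l <- .ln_bwd(dA2, cc$ln2, L$ln2_g)
    dX1 <- dX + b2l$dX
    # attention branch
    dAttn <- apply_mask(dX1, cc$m_att)
    dO <- dAttn %*% t(L$Wo)
    dWo <- crossprod(cc$O, dAttn)
    dbo <- colSums(dAttn)
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (s in seq_along(fw$lens)) {
      r <- fw$starts[s]:(fw$starts[s] + fw$lens[s] - 1L)
      for (h in seq_len(nh)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(cc$Q[r, hc, drop = FALSE],
                        cc$K[r, hc, drop = FALSE]) * scl
        S[upper.tri(S)] <- -Inf
        P <- .softmax_rows(S)
        dOh <- dO[r, hc, drop = FALSE]
        dP <- tcrossprod(dOh, cc$V[r, hc, drop = FALSE])
        dV[r, hc] <- dV[r, hc] + crossprod(P, dOh)
        dS <- P * (dP - rowSums(dP * P))
        dQ[r, hc] <- dQ[r, hc] + dS %*% cc$K[r, hc, drop = FALSE] * scl
        dK[r, hc] <- dK[r, hc] + crossprod(dS, cc$Q[r, hc, drop = FALSE]) * scl
      }
    }
    dA1 <- dQ %*% t(L$Wq) + dK %*% t(L$Wk) + dV %*% t(L$Wv)
    dWq <- crossprod(cc$A1, dQ); dbq <- colSums(dQ)
    dWk <- crossprod(cc$A1, dK); dbk <- colSums(dK)
    dWv <- crossprod(cc$A1, dV); dbv <- colSums(dV)
    b1l <- .ln_bwd(dA1, cc$ln1, L$ln1_g)
    dX <- dX1 + b1l$dX
    grads$layers[[l]] <- list(
      ln1_g = b1l$dg, ln1_b = b1l$db,
      Wq = dWq, bq = dbq, Wk = dWk, bk = dbk, Wv = dWv, bv = dbv,
      Wo = dWo, bo = dbo,
      ln2_g = b2l$dg, ln2_b = b2l$db,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  }

  dX0 <- apply_mask(dX, fw$m_emb)
  sc <- rowsum(dX0, group = fw$ids, reorder = TRUE)
  rows <- as.integer(rownames(sc)) + 1L
  grads$We[rows, ] <- grads$We[rows, ] + sc
  dWp <- matrix(0, cfg$context_len, d)
  scp <- rowsum(dX0, group = fw$pos, reorder = TRUE)
  dWp[as.integer(rownames(scp)), ] <- scp
  grads$Wp <- dWp
  grads
}

# ---- AdamW ----------------------------------------------------------------

.adamw_init <- function(params) {
  zeros <- .tree_map(function(p) p * 0, params)
  list(m = zeros, v = zeros, t = 0L)
}

.adamw_step <- function(opt, params, grads, lr, weight_decay, grad_clip,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (grad_clip > 0) {
    gnorm <- sqrt(.tree_sumsq(grads))
    if (is.finite(gnorm) && gnorm > grad_clip) {
      sc <- grad_clip / gnorm
      grads <- .tree_map(function(g) g * sc, grads)
    }
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  opt$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  params <- .tree_map(function(p, m, v) {
    step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    # decoupled decay on weight matrices only (not biases / layer norms)
    if (!is.null(dim(p))) step <- step + lr * weight_decay * p
    p - step
  }, params, opt$m, opt$v)
  list(opt = opt, params = params)
}

# ---- training -------------------------------------------------------------

#' Train the autoregressive replicon model
#'
#' Minimizes cross-entropy of next-token prediction over all positions
#' (species and Rep tokens included; evaluation later restricts to oriV
#' positions) with AdamW, shuffled minibatches, and early stopping on
#' validation loss. The returned model carries the best-validation
#' checkpoint and the full per-epoch loss log. With a fixed config seed
#' the loss trajectory is reproducible on one machine.
#'
#' @param train,valid Disjoint lists of `token_sequence` objects (or plain
#'   0-based integer id vectors).
#' @param config A [model_config()].
#' @param quiet Suppress per-epoch progress lines.
#' @return An `ori_model`: list with `config`, `params`, `training_log`
#'   (data.frame epoch/train_loss/valid_loss), `stopped_epoch`,
#'   `best_valid`.
#' @export
train_model <- function(train, valid, config, quiet = TRUE) {
  stopifnot(inherits(config, "model_config"))
  if (!length(train) || !length(valid))
    stop("train_model: empty train or validation split")
  train <- lapply(train, as.integer)
  valid <- lapply(valid, as.integer)
  old <- .save_rng(config$seed)
  on.exit(.restore_rng(old))

  params <- .init_params(config)
  opt <- .adamw_init(params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    valid_loss = numeric(0))
  best_params <- params
  best_valid <- Inf
  best_epoch <- 0L
  wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(train))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0; tn <- 0
    for (b in batches) {
      fw <- .fwd_batch(params, config, train[b], keep_cache = TRUE,
                       dropout = config$dropout)
      if (!is.finite(fw$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (loss = ", fw$loss, "); try a lower learning rate")
      gr <- .bwd_batch(params, config, fw)
      st <- .adamw_step(opt, params, gr, config$learning_rate,
                        config$weight_decay, config$grad_clip)
      opt <- st$opt; params <- st$params
      nb <- length(fw$targets)
      tl <- tl + fw$loss * nb; tn <- tn + nb
    }
    vl <- .eval_loss(params, config, valid)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tl / tn,
                                 valid_loss = vl))
    if (!quiet)
      message(sprintf("epoch %3d  train %.4f  valid %.4f", epoch, tl / tn, vl))
    if (vl < best_valid - 1e-6) {
      best_valid <- vl
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  structure(list(config = config, params = best_params, training_log = log,
                 stopped_epoch = nrow(log), best_epoch = best_epoch,
                 best_valid = best_valid),
            class = "ori_model")
}

.eval_loss <- function(params, cfg, seqs, batch_size = 32L) {
  tl <- 0; tn <- 0
  idx <- split(seq_along(seqs), ceiling(seq_along(seqs) / batch_size))
  for (b in idx) {
    fw <- .fwd_batch(params, cfg, seqs[b], keep_cache = FALSE, dropout = 0)
    nb <- length(fw$targets)
    tl <- tl + fw$loss * nb; tn <- tn + nb
  }
  tl / tn
}

#' @export
print.ori_model <- function(x, ...) {
  cat(sprintf(
    "ori_model: %d layers x %d heads, d_model %d (%.2fM params); trained %d epoch(s), best valid loss %.4f at epoch %d\n",
    x$config$n_layers, x$config$n_heads, x$config$d_model,
    count_parameters(x$config) / 1e6, x$stopped_epoch, x$best_valid,
    x$best_epoch))
  invisible(x)
}
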