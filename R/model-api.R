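#' Next-token probability distribution
#'
#' Runs a full forward pass over `prefix` (no dropout) and returns the raw
#' softmax distribution over the vocabulary for the next token. Temperature
#' is deliberately NOT applied here; sampling-time scaling lives in the
#' generation module.
#'
#' @param model An `ori_model`.
#' @param prefix A `token_sequence` or 0-based integer id vector, shorter
#'   than the context window.
#' @return Numeric probability vector of length `vocab_size` (sums to 1).
#' @export
next_token_distribution <- function(model, prefix) {
  ids <- as.integer(prefix)
  if (!length(ids)) stop("empty prefix")
  if (length(ids) >= model$config$context_len)
    stop("prefix length ", length(ids), " reaches the context window")
  lg <- .prefix_logits(model, ids)
  p <- exp(lg - max(lg))
  unname(p / sum(p))
}

.prefix_logits <- function(model, ids) {
  fw <- .fwd_batch(model$params, model$config, list(c(ids, 0L)),
                   keep_cache = FALSE, dropout = 0,
                   logits_rows = length(ids))
  # a dummy PAD token is appended so that even a length-1 prefix yields a
  # forward pass; its position is causally invisible to row length(ids)
  drop(fw$extra_logits)
}

# Total log-likelihood of a full token sequence under the model
# (sum over next-token log-probabilities; used by infill repair).
.sequence_loglik <- function(model, ids) {
  ids <- as.integer(ids)
  fw <- .fwd_batch(model$params, model$config, list(ids),
                   keep_cache = FALSE, dropout = 0)
  -fw$loss * length(fw$targets)
}

#' Mean token embedding of a sequence
#'
#' The per-sequence representation is the arithmetic mean over positions of
#' a per-token vector: by default the final-layer hidden state (contextual),
#' optionally the raw input token embedding. The choice is recorded in the
#' `embedding_type` attribute of the result.
#'
#' @param model An `ori_model`.
#' @param tokens Non-empty `token_sequence` or 0-based id vector.
#' @param type `"hidden"` (final-layer states, default) or `"input"`
#'   (token embedding rows).
#' @return Numeric vector of length `d_model` with attribute
#'   `embedding_type`.
#' @export
sequence_embedding <- function(model, tokens, type = c("hidden", "input")) {
  type <- match.arg(type)
  ids <- as.integer(tokens)
  if (!length(ids)) stop("sequence_embedding: empty token list")
  v <- if (type == "input") {
    colMeans(model$params$We[ids + 1L, , drop = FALSE])
  } else {
    fw <- .fwd_batch(model$params, model$config, list(ids),
                     keep_cache = FALSE, dropout = 0)
    colMeans(fw$H)
  }
  structure(unname(v), embedding_type = type)
}

#' Save / load a model checkpoint directory
#'
#' The directory holds the serialized weights (`weights.rds`), the model
#' configuration as a plain-text key=value file (`config.txt`), the
#' vocabulary (`vocab.txt`, if supplied) and the training log as TSV.
#'
#' @param model An `ori_model`.
#' @param dir Checkpoint directory (created if needed).
#' @param vocab Optional `ori_vocabulary` to store alongside.
#' @export
save_model <- function(model, dir, vocab = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  cfg <- model$config
  writeLines(paste0(names(cfg), "=", vapply(cfg, format, character(1))),
             file.path(dir, "config.txt"))
  write.table(model$training_log, file.path(dir, "training_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  extra <- data.frame(key = c("stopped_epoch", "best_epoch", "best_valid"),
                      value = c(model$stopped_epoch, model$best_epoch,
                                model$best_valid))
  write.table(extra, file.path(dir, "state.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(vocab)) write_vocabulary(vocab, file.path(dir, "vocab.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @return `load_model`: the restored `ori_model`.
#' @export
load_model <- function(dir) {
  kv <- strsplit(readLines(file.path(dir, "config.txt")), "=", fixed = TRUE)
  cfg <- setNames(lapply(kv, function(x) {
    v <- x[[2L]]
    if (grepl("^-?[0-9.e+-]+$", v)) as.numeric(v) else v
  }), vapply(kv, `[[`, character(1), 1L))
  config <- do.call(model_config, cfg[setdiff(names(cfg), character(0))])
  log <- read.delim(file.path(dir, "training_log.tsv"))
  st <- read.delim(file.path(dir, "state.tsv"))
  vals <- setNames(st$value, st$key)
  structure(list(config = config,
                 params = readRDS(file.path(dir, "weights.rds")),
                 training_log = log,
                 stopped_epoch = as.integer(vals[["stopped_epoch"]]),
                 best_epoch = as.integer(vals[["best_epoch"]]),
                 best_valid = as.numeric(vals[["best_valid"]])),
            class = "ori_model")
}

# ---- incremental decoding with per-layer key/value caches -----------------
# Equivalent to the full forward pass position by position (verified in the
# test suite); makes autoregressive generation O(T^2 d) instead of O(T^3 d).

.decoder_init <- function(model, max_len) {
  cfg <- model$config
  max_len <- min(max_len, cfg$context_len)
  list(n = 0L, max_len = max_len,
       layers = lapply(seq_len(cfg$n_layers), function(l) {
         list(K = matrix(0, max_len, cfg$d_model),
              V = matrix(0, max_len, cfg$d_model))
       }))
}

.ln_vec <- function(x, g, b) {
  mu <- mean(x)
  xc <- x - mu
  inv <- 1 / sqrt(mean(xc * xc) + LN_EPS)
  (xc * inv) * g + b
}

# Feed one token id (0-based); returns list(state, logits) where logits is
# the unnormalized log-probability vector for the NEXT token.
.decoder_step <- function(model, state, id) {
  cfg <- model$config
  P <- model$params
  n <- state$n + 1L
  if (n > state$max_len) stop("decoder cache exhausted at position ", n)
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  scl <- 1 / sqrt(dh)
  x <- P$We[id + 1L, ] + P$Wp[n, ]
  for (l in seq_len(cfg$n_layers)) {
    L <- P$layers[[l]]
    a1 <- .ln_vec(x, L$ln1_g, L$ln1_b)
    q <- drop(a1 %*% L$Wq) + L$bq
    state$layers[[l]]$K[n, ] <- drop(a1 %*% L$Wk) + L$bk
    state$layers[[l]]$V[n, ] <- drop(a1 %*% L$Wv) + L$bv
    Kc <- state$layers[[l]]$K[seq_len(n), , drop = FALSE]
    Vc <- state$layers[[l]]$V[seq_len(n), , drop = FALSE]
    o <- numeric(d)
    for (h in seq_len(nh)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      s <- drop(Kc[, hc, drop = FALSE] %*% q[hc]) * scl
      p <- exp(s - max(s)); p <- p / sum(p)
      o[hc] <- drop(p %*% Vc[, hc, drop = FALSE])
    }
    x1 <- x + drop(o %*% L$Wo) + L$bo
    a2 <- .ln_vec(x1, L$ln2_g, L$ln2_b)
    h1 <- .gelu(drop(a2 %*% L$W1) + L$b1)
    x <- x1 + drop(h1 %*% L$W2) + L$b2
  }
  h <- .ln_vec(x, P$lnf_g, P$lnf_b)
  state$n <- n
  list(state = state, logits = drop(P$We %*% h))
}
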