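#' Configuration for the decoder-only autoregressive replicon model
#'
#' Defaults mirror the reference architecture: 12 transformer layers with
#' 12 attention heads each, embedding dimension 768 (feed-forward 4x),
#' a 1500-token context window, dropout 0.1 and weight decay 0.1 under
#' AdamW. The output head is tied to the token embedding matrix and
#' positional embeddings are learned absolute positions.
#'
#' @param vocab_size Number of tokens in the vocabulary.
#' @param n_layers,n_heads,d_model,d_ff Architecture dimensions;
#'   `d_model` must be divisible by `n_heads`.
#' @param context_len Maximum sequence length in tokens.
#' @param dropout Dropout probability applied to embeddings and to each
#'   residual branch during training.
#' @param weight_decay Decoupled AdamW weight decay for weight matrices.
#' @param learning_rate AdamW step size (constant schedule).
#' @param batch_size Sequences per optimizer step.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @param grad_clip Global gradient-norm clip (0 disables).
#' @param seed Seed controlling initialization and data shuffling.
#' @return A `model_config` list.
#' @export
model_config <- function(vocab_size,
                         n_layers = 12L, n_heads = 12L, d_model = 768L,
                         d_ff = 4L * d_model, context_len = 1500L,
                         dropout = 0.1, weight_decay = 0.1,
                         learning_rate = 3e-3, batch_size = 16L,
                         max_epochs = 50L, patience = 5L,
                         grad_clip = 1.0, seed = 1L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              d_model = as.integer(d_model), d_ff = as.integer(d_ff),
              context_len = as.integer(context_len),
              dropout = dropout, weight_decay = weight_decay,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              grad_clip = grad_clip, seed = as.integer(seed))
  if (cfg$d_model %% cfg$n_heads != 0L)
    stop("d_model must be divisible by n_heads")
  if (cfg$vocab_size < 5L) stop("vocab_size too small")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  class(cfg) <- "model_config"
  cfg
}

#' Exact trainable-parameter count of a model configuration
#'
#' Closed form for the architecture actually instantiated: token embedding
#' (vocab x d), learned positional embedding (context x d), per layer the
#' four d x d attention projections with biases, the two feed-forward
#' matrices with biases, and two layer norms; plus the final layer norm.
#' The output head is tied to the token embedding and contributes no
#' additional parameters. The reference configuration (12 layers, 12
#' heads, d = 768, vocab 145, context 1500) counts 86,319,360, i.e. 86M
#' rounded to millions.
#'
#' @param config A [model_config()].
#' @return Integer-valued numeric parameter count.
#' @examples
#' cfg <- model_config(vocab_size = 145)
#' round(count_parameters(cfg) / 1e6)  # 86
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d_model
  dff <- config$d_ff
  per_layer <- 4 * d * d + 4 * d +          # Q, K, V, output projections
    d * dff + dff + dff * d + d +           # feed-forward in / out
    2 * (2 * d)                             # two layer norms (gain + bias)
  config$vocab_size * d +                   # token embedding (tied head)
    config$context_len * d +                # positional embedding
    config$n_layers * per_layer +
    2 * d                                   # final layer norm
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "model_config: %d layers x %d heads, d_model %d, d_ff %d, context %d, vocab %d (%.2fM params)\n",
    x$n_layers, x$n_heads, x$d_model, x$d_ff, x$context_len, x$vocab_size,
    count_parameters(x) / 1e6))
  invisible(x)
}
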