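#' Generation configuration
#'
#' Bundles the sampling mode and its parameters, the conditioning prompt,
#' the forbidden-motif set for constrained decoding, the length/stop
#' policy and the seed. Defaults follow the reference settings: nucleus
#' sampling with `top_p = 0.95`, `temperature = 1.0`, and `top_k = 4` for
#' top-k mode.
#'
#' @param prompt A `token_sequence` prompt from [make_prompt()] (at minimum
#'   the `<bos>` token).
#' @param mode `"nucleus"`, `"topk"` or `"beam"`.
#' @param top_p Nucleus mass threshold in (0, 1].
#' @param top_k Number of tokens kept in top-k mode.
#' @param temperature Positive logit temperature; values below `1e-8` are
#'   treated as the argmax limit.
#' @param n_beams Beam width for `"beam"` mode.
#' @param forbidden An `expanded_motif_set` from [expand_motifs()] (only
#'   allowed, and required, in beam mode).
#' @param max_len Total token-length cap, prompt included.
#' @param seed Integer seed.
#' @return A `generation_config` list.
#' @export
generation_config <- function(prompt, mode = c("nucleus", "topk", "beam"),
                              top_p = 0.95, top_k = 4L, temperature = 1.0,
                              n_beams = 8L, forbidden = NULL,
                              max_len = 400L, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(prompt)) stop("prompt must contain at least the <bos> token")
  if (top_p <= 0 || top_p > 1) stop("top_p must be in (0, 1]")
  if (top_k < 1L) stop("top_k must be >= 1")
  if (temperature < 0) stop("temperature must be non-negative")
  if (!is.null(forbidden) && length(forbidden) && mode != "beam")
    stop("forbidden motifs require beam mode; use generate_constrained()")
  structure(list(prompt = as.integer(prompt), mode = mode, top_p = top_p,
                 top_k = as.integer(top_k), temperature = temperature,
                 n_beams = as.integer(n_beams), forbidden = forbidden,
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "generation_config")
}

#' Truncate a probability distribution for nucleus or top-k sampling
#'
#' Nucleus: the smallest prefix of the probability-sorted tokens whose
#' cumulative mass reaches `top_p` is kept and renormalized. Top-k: the
#' `k` most probable tokens are kept and renormalized. Ties are broken by
#' index (ascending), making the kept set deterministic.
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @param mode `"nucleus"` or `"topk"`.
#' @param top_p,top_k Mode parameters.
#' @return Probability vector of the same length, zero outside the kept
#'   set, renormalized over it.
#' @export
truncate_distribution <- function(p, mode = c("nucleus", "topk"),
                                  top_p = 0.95, top_k = 4L) {
  mode <- match.arg(mode)
  ord <- order(-p, seq_along(p))
  keep <- if (mode == "nucleus") {
    cum <- cumsum(p[ord])
    ord[seq_len(which(cum >= top_p - 1e-12)[1L])]
  } else {
    ord[seq_len(min(top_k, sum(p > 0)))]
  }
  out <- numeric(length(p))
  out[keep] <- p[keep]
  out / sum(out)
}

# ---- token-layout grammar -------------------------------------------------
# Sampled continuations are restricted to ids that keep the sequence a
# valid layout prefix, so every finished generation decodes to a
# replicon_record. States mirror the decode_tokens() grammar.

.grammar_init <- function(vocab) {
  sp <- special_ids(vocab)
  list(sp = sp,
       species = class_ids(vocab, "SPECIES"),
       aa = class_ids(vocab, "AMINO_ACID"),
       nuc = class_ids(vocab, "NUCLEOTIDE"))
}

.grammar_state_of <- function(ids, g) {
  state <- "AT_START"
  for (id in ids) state <- .grammar_next(state, id, g)
  state
}

.grammar_next <- function(state, id, g) {
  sp <- g$sp
  if (state == "AT_START") return("AT_BOS")
  if (id %in% g$nuc) return("IN_ORIV")
  if (id %in% g$aa) return("IN_REP")
  if (id == sp[["sep"]]) return("AFTER_SEP")
  if (id == sp[["eos"]]) return("DONE")
  "AFTER_SPECIES"  # species token or <unk_species>
}

.grammar_allowed <- function(state, g) {
  sp <- g$sp
  switch(state,
    AT_START = sp[["bos"]],
    AT_BOS = c(g$species, sp[["unk_species"]]),
    AFTER_SPECIES = c(g$aa, g$nuc),
    IN_REP = c(g$aa, sp[["sep"]], g$nuc),
    AFTER_SEP = g$aa,
    IN_ORIV = c(g$nuc, sp[["eos"]]),
    stop("generation grammar: no continuation from state ", state))
}

# ---- sampling-mode generation ---------------------------------------------

#' Generate replicon sequences by sampling
#'
#' Autoregressive sampling from a trained model under the configured
#' truncation rule (nucleus or top-k) after temperature scaling of the
#' logits. Each output starts with the prompt verbatim; generation stops
#' at `<eos>` or at the `max_len` token cap. Continuations are restricted
#' to the token-layout grammar so outputs always decode. A fixed seed
#' yields identical outputs.
#'
#' @param model An `ori_model`.
#' @param vocab The `ori_vocabulary` the model was trained with.
#' @param config A [generation_config()] with mode `"nucleus"` or `"topk"`.
#' @param n Number of sequences to sample.
#' @return List of [replicon_record()]; each carries attributes `tokens`
#'   (the generated `token_sequence`) and `truncated`.
#' @export
generate <- function(model, vocab, config, n = 1L) {
  stopifnot(inherits(config, "generation_config"))
  if (config$mode == "beam")
    stop("beam mode is handled by generate_constrained()")
  g <- .grammar_init(vocab)
  .check_prompt(config$prompt, g)
  old <- .save_rng(config$seed)
  on.exit(.restore_rng(old))
  lapply(seq_len(n), function(i) {
    .sample_one(model, vocab, config, g, sample_id = i)
  })
}

.check_prompt <- function(prompt, g) {
  state <- "AT_START"
  for (j in seq_along(prompt)) {
    if (!prompt[j] %in% .grammar_allowed(state, g))
      stop("prompt violates the token-layout grammar at position ", j - 1L)
    state <- .grammar_next(state, prompt[j], g)
  }
  invisible(state)
}

.sample_one <- function(model, vocab, config, g, sample_id) {
  eos <- g$sp[["eos"]]
  state <- .decoder_init(model, config$max_len)
  ids <- config$prompt
  for (id in ids) {
    st <- .decoder_step(model, state, id)
    state <- st$state
  }
  parse_state <- .grammar_state_of(ids, g)
  logits <- st$logits
  truncated <- FALSE
  repeat {
    allowed <- .grammar_allowed(parse_state, g)
    id <- .sample_token(logits, allowed, config)
    ids <- c(ids, id)
    if (id == eos) break
    if (length(ids) >= config$max_len) {
      truncated <- TRUE
      break
    }
    parse_state <- .grammar_next(parse_state, id, g)
    st <- .decoder_step(model, state, id)
    state <- st$state
    logits <- st$logits
  }
  rec <- decode_tokens(new_token_sequence(ids), vocab,
                       record_id = sprintf("gen_%s_%03d", config$mode,
                                           sample_id),
                       allow_truncated = TRUE)
  attr(rec, "tokens") <- new_token_sequence(ids)
  attr(rec, "truncated") <- truncated
  rec
}

.sample_token <- function(logits, allowed, config) {
  lg <- rep(-Inf, length(logits))
  lg[allowed + 1L] <- logits[allowed + 1L]
  if (config$temperature < 1e-8) {
    ok <- which(is.finite(lg))
    return(ok[which.max(lg[ok])] - 1L)  # argmax limit, ties by token id
  }
  lg <- lg / config$temperature
  p <- exp(lg - max(lg))
  p <- p / sum(p)
  q <- truncate_distribution(p, mode = config$mode, top_p = config$top_p,
                             top_k = config$top_k)
  sample.int(length(q), 1L, prob = q) - 1L
}
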