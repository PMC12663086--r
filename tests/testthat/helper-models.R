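# Trained-model fixtures are expensive, so they are built lazily and
# memoized for the whole test run. Seeds and corpus conditions are fixed
# here once; individual tests must not change them.

.model_cache <- new.env(parent = emptyenv())

helper_cached <- function(key, builder) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, builder(), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

# Single-sequence memorization model (tiny config).
helper_memo_model <- function() {
  helper_cached("memo", function() {
    rec <- replicon_record("memo1", "Escherichia_coli", character(),
                          "acgtacggttacgtacaatgcgt")
    vocab <- build_vocabulary(list(rec))
    tok <- encode_replicon(rec, vocab)
    cfg <- model_config(vocab_size = vocab_size(vocab), n_layers = 2,
                        n_heads = 2, d_model = 64, d_ff = 256,
                        context_len = 64, dropout = 0,
                        learning_rate = 3e-3, batch_size = 16,
                        max_epochs = 40, patience = 40, seed = 11)
    model <- train_model(rep(list(tok), 100), list(tok), cfg)
    list(model = model, vocab = vocab, record = rec, tokens = tok)
  })
}

# The 2-family synthetic corpus (generator defaults) with a tiny model
# trained on a 75/25 random record split.
helper_corpus_model <- function() {
  helper_cached("corpus", function() {
    corpus <- make_corpus(synthetic_spec(seed = 101))
    vocab <- build_vocabulary(corpus$records)
    toks <- lapply(corpus$records, encode_replicon, vocab = vocab,
                   context_len = 512L)
    set.seed(202)
    part <- ifelse(runif(length(toks)) < 0.25, "VALID", "TRAIN")
    cfg <- model_config(vocab_size = vocab_size(vocab), n_layers = 2,
                        n_heads = 2, d_model = 64, d_ff = 256,
                        context_len = 512, dropout = 0,
                        learning_rate = 3e-3, batch_size = 16,
                        max_epochs = 30, patience = 6, seed = 7)
    model <- train_model(toks[part == "TRAIN"], toks[part == "VALID"], cfg)
    list(model = model, vocab = vocab, corpus = corpus, part = part)
  })
}

# Tiny model trained on GATC-saturated synthetic records: one species,
# one 60-nt template carrying six gatc sites, 2% substitution noise.
helper_gatc_model <- function() {
  helper_cached("gatc", function() {
    set.seed(501)
    spacer <- function(n) {
      # spacers free of g so no accidental gatc can form at joints
      paste(sample(c("a", "c", "t"), n, replace = TRUE), collapse = "")
    }
    template <- paste0(spacer(5), paste(rep(paste0("gatc", spacer(5)), 6),
                                        collapse = ""), spacer(3))
    recs <- lapply(1:80, function(i) {
      chars <- strsplit(template, "", fixed = TRUE)[[1L]]
      hit <- which(runif(length(chars)) < 0.02)
      for (k in hit) chars[k] <- sample(setdiff(c("a", "c", "g", "t"),
                                                chars[k]), 1L)
      replicon_record(sprintf("gatc_%03d", i), "Escherichia_coli",
                      character(), paste(chars, collapse = ""))
    })
    vocab <- build_vocabulary(recs)
    toks <- lapply(recs, encode_replicon, vocab = vocab)
    cfg <- model_config(vocab_size = vocab_size(vocab), n_layers = 2,
                        n_heads = 2, d_model = 48, d_ff = 192,
                        context_len = 128, dropout = 0,
                        learning_rate = 3e-3, batch_size = 16,
                        max_epochs = 25, patience = 25, seed = 13)
    model <- train_model(toks[1:64], toks[65:80], cfg)
    list(model = model, vocab = vocab, records = recs,
         template = template)
  })
}
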