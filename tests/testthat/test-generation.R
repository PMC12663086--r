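test_that("IUPAC expansion produces reverse-complement-closed sets", {
  expect_identical(as.character(expand_motifs("GATC")), "GATC")
  expect_setequal(as.character(expand_motifs("CCWGG")), c("CCAGG", "CCTGG"))
  expect_setequal(as.character(expand_motifs("GGTCTC")),
                  c("GGTCTC", "GAGACC"))
  full <- expand_motifs(make_motif_fixture())
  rc <- vapply(full, oriforge:::.revcomp_upper, character(1))
  expect_true(all(rc %in% full))  # closure
  expect_false(any(grepl("[^ACGT]", full)))
  expect_error(expand_motifs("GAXC"), "invalid IUPAC character 'X'")
  expect_error(expand_motifs("GA"), "shorter than three")
  expect_error(expand_motifs("NNNNNNAT"), "more than five degenerate")
})

test_that("distribution truncation matches a brute-force reference", {
  # worked example: top-p 0.95 keeps exactly the two largest masses
  q <- truncate_distribution(c(0.9, 0.06, 0.03, 0.01), "nucleus",
                             top_p = 0.95)
  expect_equal(which(q > 0), c(1, 2))
  expect_equal(sum(q), 1)

  brute_nucleus <- function(p, top_p) {
    ord <- order(p, decreasing = TRUE)
    kept <- integer(0); mass <- 0
    for (i in ord) {
      kept <- c(kept, i); mass <- mass + p[i]
      if (mass >= top_p - 1e-12) break
    }
    sort(kept)
  }
  brute_topk <- function(p, k) sort(order(p, decreasing = TRUE)[1:k])
  set.seed(8)
  for (rep in 1:25) {
    p <- runif(10); p <- p / sum(p)
    tp <- runif(1, 0.2, 0.99)
    q <- truncate_distribution(p, "nucleus", top_p = tp)
    expect_equal(which(q > 0), brute_nucleus(p, tp))
    expect_equal(sum(q), 1, tolerance = 1e-12)
    k <- sample(1:10, 1)
    qk <- truncate_distribution(p, "topk", top_k = k)
    expect_equal(which(qk > 0), brute_topk(p, k))
  }
})

test_that("sampling preserves the prompt, stops at EOS, and is seeded", {
  memo <- helper_memo_model()
  v <- memo$vocab
  prompt <- make_prompt(v, species = "Escherichia_coli", oriv_seed = "acgta")
  cfg <- generation_config(prompt = prompt, mode = "nucleus", max_len = 64,
                           seed = 21)
  out <- generate(memo$model, v, cfg, n = 5)
  for (r in out) {
    toks <- attr(r, "tokens")
    expect_identical(as.integer(toks)[seq_along(prompt)],
                     as.integer(prompt))
    expect_true(startsWith(r$oriv, "acgta"))
  }
  # identical config + seed => identical outputs
  out2 <- generate(memo$model, v, cfg, n = 5)
  expect_identical(vapply(out, `[[`, character(1), "oriv"),
                   vapply(out2, `[[`, character(1), "oriv"))

  # temperature -> 0 on a memorized model reproduces the sequence; and
  # top_k = 1 equals argmax decoding
  p0 <- make_prompt(v, species = "Escherichia_coli")
  argmax <- generate(memo$model, v, generation_config(
    prompt = p0, mode = "nucleus", temperature = 0, max_len = 64,
    seed = 1))[[1]]
  expect_identical(argmax$oriv, memo$record$oriv)
  top1 <- generate(memo$model, v, generation_config(
    prompt = p0, mode = "topk", top_k = 1, max_len = 64, seed = 9))[[1]]
  expect_identical(top1$oriv, argmax$oriv)

  # layout-grammar violations in the prompt are rejected
  nt <- class_ids(v, "NUCLEOTIDE")
  bad <- oriforge:::new_token_sequence(c(special_ids(v)[["bos"]], nt[1]))
  expect_error(generate(memo$model, v,
                        generation_config(prompt = bad, max_len = 16)),
               "grammar")
})

test_that("constrained beam search excludes forbidden motifs", {
  gm <- helper_gatc_model()
  v <- gm$vocab
  forbidden <- expand_motifs("GATC")
  prompt <- make_prompt(v, species = "Escherichia_coli")
  cfg <- generation_config(prompt = prompt, mode = "beam", n_beams = 10,
                           forbidden = forbidden, max_len = 100, seed = 1)
  out <- generate_constrained(gm$model, v, cfg)
  expect_gt(length(out), 0)
  for (r in out) {
    expect_equal(helper_count_motifs_both_strands(r$oriv, "GATC"), 0)
  }
  # ranked by total log-likelihood
  lls <- vapply(out, function(r) attr(r, "loglik"), numeric(1))
  expect_true(all(diff(lls) <= 1e-9))
  # deterministic
  out2 <- generate_constrained(gm$model, v, cfg)
  expect_identical(vapply(out, `[[`, character(1), "oriv"),
                   vapply(out2, `[[`, character(1), "oriv"))

  # empty forbidden set points the caller at generate()
  expect_error(
    generate_constrained(gm$model, v,
                         generation_config(prompt = prompt, mode = "beam",
                                           forbidden = NULL, max_len = 50)),
    "generate\\(\\)")
  # a seed that carries a forbidden motif must be repaired first
  bad <- generation_config(
    prompt = make_prompt(v, species = "Escherichia_coli",
                         oriv_seed = "agatca"),
    mode = "beam", n_beams = 4, forbidden = forbidden, max_len = 50)
  expect_error(generate_constrained(gm$model, v, bad), "infill_repair")
})

test_that("infill repair clears motifs with minimal model-guided edits", {
  gm <- helper_gatc_model()
  forbidden <- expand_motifs("GATC")
  clean <- "ggttccaa"
  out <- infill_repair(clean, forbidden, gm$model, gm$vocab,
                       species = "Escherichia_coli")
  expect_identical(as.character(out), clean)
  expect_equal(attr(out, "n_edits"), 0L)

  dirty <- "ggatcc"
  rep1 <- infill_repair(dirty, forbidden, gm$model, gm$vocab,
                        species = "Escherichia_coli")
  expect_equal(helper_count_motifs_both_strands(rep1, "GATC"), 0)
  expect_equal(nchar(rep1), nchar(dirty))
  expect_gte(attr(rep1, "n_edits"), 1L)
  diff_at <- which(strsplit(as.character(rep1), "")[[1]] !=
                     strsplit(dirty, "")[[1]])
  expect_true(all(diff_at >= 2 & diff_at <= 5))  # inside the gatc window
  # idempotence (fixed point)
  rep2 <- infill_repair(as.character(rep1), forbidden, gm$model, gm$vocab,
                        species = "Escherichia_coli")
  expect_identical(as.character(rep2), as.character(rep1))
  expect_equal(attr(rep2, "n_edits"), 0L)
})
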