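test_that("vocabulary construction counts classes and is order-independent", {
  recs <- list(
    replicon_record("r1", "Escherichia_coli", c("MKV"), "acgt"),
    replicon_record("r2", "Bacillus_subtilis", character(), "ttga"),
    replicon_record("r3", "Escherichia_coli", c("AC", "WY"), "acgtacgt"))
  v <- build_vocabulary(recs)
  expect_equal(vocab_size(v), 5 + 2 + 20 + 4)
  expect_equal(sum(v$class_of == "NUCLEOTIDE"), 4)
  expect_equal(sum(v$class_of == "AMINO_ACID"), 20)
  # bijective, contiguous from 0
  expect_equal(sort(unname(v$token_to_id)), 0:(vocab_size(v) - 1))
  # permutation invariance
  v2 <- build_vocabulary(recs[c(3, 1, 2)])
  expect_identical(v$token_to_id, v2$token_to_id)

  # all-unknown species: no SPECIES tokens
  vu <- build_vocabulary(list(replicon_record("u1", NA, character(), "ac")))
  expect_equal(vocab_size(vu), 29)
  expect_equal(sum(vu$class_of == "SPECIES"), 0)

  expect_error(build_vocabulary(list()), "empty")
  expect_error(replicon_record("bad", "X", character(), "acgX"),
               "record 'bad'.*offset 3")
  expect_error(replicon_record("bad2", "X", "MKv", "acgt"), "record 'bad2'")
})

test_that("vocabulary round-trips through its plain-text serialization", {
  recs <- list(replicon_record("r1", "Escherichia_coli", "MK", "acgt"))
  v <- build_vocabulary(recs)
  path <- withr::local_tempfile(fileext = ".txt")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path)
  expect_identical(v$token_to_id, v2$token_to_id)
  expect_identical(v$class_of, v2$class_of)
})

test_that("encoding follows the layout and inverts exactly", {
  recs <- list(
    replicon_record("r1", "Sp_a", character(), "acgt"),
    replicon_record("r2", "Sp_b", c("MKV", "AC"), "acgt"))
  v <- build_vocabulary(recs)
  sp <- special_ids(v)

  t1 <- encode_replicon(recs[[1]], v)
  expect_length(t1, 7)  # BOS, species, a, c, g, t, EOS
  expect_equal(t1[1], unname(sp[["bos"]]))
  expect_equal(t1[7], unname(sp[["eos"]]))

  # 2 Reps of lengths 3 and 2, oriV length 4: 1+1+3+1+2+4+1 = 13
  t2 <- encode_replicon(recs[[2]], v)
  expect_length(t2, 13)
  expect_equal(sum(t2 == sp[["sep"]]), 1)

  # unknown species maps to <unk_species>
  ru <- replicon_record("ru", NA, character(), "gg")
  expect_equal(encode_replicon(ru, v)[2], unname(sp[["unk_species"]]))

  # context-window rejection carries the measured length
  expect_error(encode_replicon(recs[[2]], v, context_len = 10), "13 tokens")
})

test_that("encode/decode round trip is the identity on random records", {
  set.seed(42)
  recs <- lapply(sprintf("rr%03d", 1:100), helper_random_record)
  v <- build_vocabulary(recs)
  for (r in recs) {
    r2 <- decode_tokens(encode_replicon(r, v), v, record_id = r$record_id)
    expect_identical(r2$oriv, r$oriv)
    expect_identical(r2$rep_proteins, r$rep_proteins)
    expect_identical(r2$host_species, r$host_species)
  }
})

test_that("malformed token sequences raise parse errors with positions", {
  recs <- list(replicon_record("r1", "Sp_a", "MK", "acgt"))
  v <- build_vocabulary(recs)
  sp <- special_ids(v)
  ids <- as.integer(encode_replicon(recs[[1]], v))

  expect_error(decode_tokens(ids[-length(ids)][1:4], v),
               "oriV nucleotide")
  # <sep> with no following Rep tokens
  nt <- class_ids(v, "NUCLEOTIDE")
  bad <- c(sp[["bos"]], v$token_to_id[["Sp_a"]], v$token_to_id[["M"]],
           sp[["sep"]], nt[1], sp[["eos"]])
  expect_error(decode_tokens(bad, v), "<sep> with no following Rep")
  # nucleotide before species
  bad2 <- c(sp[["bos"]], nt[1], nt[2], sp[["eos"]])
  expect_error(decode_tokens(bad2, v), "species")
  # trailing tokens after <eos>
  expect_error(decode_tokens(c(ids, nt[1]), v), "trailing")
  # truncated oriV accepted only when allowed
  cut <- ids[seq_len(length(ids) - 1L)]
  expect_error(decode_tokens(cut, v), "missing <eos>")
  rec <- decode_tokens(cut, v, allow_truncated = TRUE)
  expect_identical(rec$oriv, recs[[1]]$oriv)
})

test_that("identity clustering groups near-identical sequences only", {
  set.seed(7)
  # two identical sequences cluster together
  s <- helper_random_seq(120)
  sp <- cluster_and_split(c(a = s, b = s, c = helper_random_seq(120)),
                          seed = 3)
  expect_equal(sp$cluster[sp$record_id == "a"],
               sp$cluster[sp$record_id == "b"])
  expect_false(sp$cluster[sp$record_id == "c"] ==
                 sp$cluster[sp$record_id == "a"])

  # mutually <90%-identical random 200-mers found distinct clusters
  seqs <- setNames(replicate(6, helper_random_seq(200)), paste0("q", 1:6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_lt(global_align(seqs[[i]], seqs[[j]])$identity_pct, 0.9)
  }
  sp2 <- cluster_and_split(seqs, seed = 5)
  expect_equal(length(unique(sp2$cluster)), 6)

  # same seed: identical partition; cluster-level partition
  sp3 <- cluster_and_split(seqs, seed = 5)
  expect_identical(sp2, sp3)
  agg <- tapply(sp2$partition, sp2$cluster, function(x) length(unique(x)))
  expect_true(all(agg == 1))

  expect_error(cluster_and_split(seqs, identity_threshold = 1.5),
               "identity_threshold")
  expect_error(cluster_and_split(seqs[1]), "at least 2")
})

test_that("cluster split hits the target fraction for many clusters", {
  set.seed(11)
  seqs <- setNames(replicate(48, helper_random_seq(60)), paste0("c", 1:48))
  sp <- cluster_and_split(seqs, seed = 17)
  n_cl <- length(unique(sp$cluster))
  expect_gte(n_cl, 40)
  valid_frac <- length(unique(sp$cluster[sp$partition == "VALID"])) / n_cl
  expect_lt(abs(valid_frac - 0.25), 0.05)
})

test_that("near-duplicate filtering removes contained high-identity hits", {
  set.seed(19)
  train <- setNames(replicate(3, helper_random_seq(300)), paste0("t", 1:3))
  mut96 <- apply_matched_mutations(train[[1]],
                                   mutant_spec(n_sub = 10, seed = 2))
  aln <- global_align(mut96, train[[1]])
  expect_gt(aln$identity_pct, 0.95)  # construction check via the aligner
  test <- c(dup = unname(train[[1]]), far = helper_random_seq(300),
            near = mut96)
  kept <- filter_near_duplicates(test, train)
  expect_false("dup" %in% kept)
  expect_false("near" %in% kept)
  expect_true("far" %in% kept)
  # idempotence
  kept2 <- filter_near_duplicates(test[kept], train)
  expect_identical(sort(kept2), sort(kept))
  expect_error(filter_near_duplicates(character(0), train), "non-empty")
})

test_that("replicon corpora round-trip through manifest + FASTA files", {
  set.seed(23)
  recs <- lapply(sprintf("io%02d", 1:12), helper_random_record)
  dir <- withr::local_tempdir()
  write_replicons(recs, dir, prefix = "x")
  back <- read_replicons(file.path(dir, "x_manifest.tsv"),
                         file.path(dir, "x_oriv.fasta"),
                         file.path(dir, "x_rep.fasta"))
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$oriv, recs[[i]]$oriv)
    expect_identical(back[[i]]$rep_proteins, recs[[i]]$rep_proteins)
    expect_identical(back[[i]]$host_species, recs[[i]]$host_species)
  }
})
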