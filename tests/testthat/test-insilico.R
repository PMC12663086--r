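test_that("AT content is exact and reverse-complement invariant", {
  expect_equal(at_content("atat"), 1.0)
  expect_equal(at_content("gcgc"), 0.0)
  expect_equal(at_content("atgc"), 0.5)
  set.seed(3)
  for (i in 1:10) {
    s <- helper_random_seq(50)
    rc <- oriforge:::.revcomp_upper(toupper(s))
    expect_equal(at_content(s), at_content(tolower(rc)))
    expect_true(at_content(s) >= 0 && at_content(s) <= 1)
  }
  expect_error(at_content(""), "empty")
  expect_error(at_content("acgn"), "invalid")
})

test_that("windowed folding energy slides, plugs and bounds correctly", {
  s100 <- helper_random_seq(100)
  one <- windowed_mfe(s100)
  expect_length(one$values, 1)

  s <- helper_random_seq(140)
  res <- windowed_mfe(s, window = 100)
  expect_length(res$values, 140 - 99)
  expect_true(all(res$values <= 0))  # stand-in energy is never positive
  expect_equal(res$mean, mean(res$values))

  # homopolymer: no complementary bases, every window scores 0
  homo <- windowed_mfe(strrep("a", 120), window = 100)
  expect_true(all(homo$values == 0))

  # pluggable engine
  const <- windowed_mfe(s, window = 100, engine = function(w) -1)
  expect_true(all(const$values == -1))

  # stem-loop sanity for the Nussinov stand-in
  expect_equal(nussinov_energy("gggaaaaccc"), -3)
  expect_equal(nussinov_energy("acgt"), 0)  # loop constraint blocks pairs
  expect_error(windowed_mfe("acgt", window = 100), "shorter")
})

test_that("PWM scanning matches hand-computed scores on both strands", {
  # sharp 6-mer: consensus scores maximally at its planted offset
  probs <- matrix(0.01, 6, 4)
  consensus <- c(1, 3, 4, 4, 2, 1)  # a g t t c a
  probs[cbind(1:6, consensus)] <- 0.97
  p <- pwm("sharp6", probs)
  seq20 <- paste0("cccccc", "agttca", "cccccccc")
  hits <- scan_pwm(seq20, p)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, 6)
  expect_equal(plus$score, 6 * log(0.97 / 0.25), tolerance = 1e-9)

  # hand-summed score of a mismatched window
  code <- match(strsplit("agttcc", "")[[1]], c("a", "c", "g", "t"))
  hand <- sum(log(probs[cbind(1:6, code)] / 0.25))
  seq2 <- paste0("tttttt", "agttcc", "tttttt")
  sc <- scan_pwm(seq2, pwm("x", probs, score_threshold = -Inf))
  expect_equal(sc$score[sc$start == 6 & sc$strand == "+"], hand,
               tolerance = 1e-9)

  # uniform PWM scores 0 everywhere: no hits above threshold 1.0
  expect_equal(nrow(scan_pwm(seq20, pwm("flat", matrix(0.25, 8, 4)))), 0)

  # PWM longer than the sequence: zero hits, not an error
  expect_equal(nrow(scan_pwm("acgt", p)), 0)

  # reverse-complementing the sequence mirrors hits onto the other strand
  s <- paste0("gg", "agttca", "ccaa")
  h_fwd <- scan_pwm(s, p)
  s_rc <- tolower(oriforge:::.revcomp_upper(toupper(s)))
  h_rc <- scan_pwm(s_rc, p)
  expect_equal(nrow(h_fwd), nrow(h_rc))
  n <- nchar(s)
  for (k in seq_len(nrow(h_fwd))) {
    mirrored <- h_rc[h_rc$start == n - h_fwd$end[k] &
                       h_rc$strand != h_fwd$strand[k], ]
    expect_equal(nrow(mirrored), 1)
    expect_equal(mirrored$score, h_fwd$score[k], tolerance = 1e-9)
  }
})

test_that("motif presence profiles count per motif and flag joint presence", {
  probs_a <- matrix(0.01, 5, 4); probs_a[cbind(1:5, c(1, 1, 3, 3, 1))] <- 0.97
  probs_b <- matrix(0.01, 5, 4); probs_b[cbind(1:5, c(2, 3, 2, 3, 2))] <- 0.97
  pa <- pwm("ma", probs_a); pb <- pwm("mb", probs_b)
  both <- paste0("aagga", "tt", "cgcgc")
  prof <- motif_presence_profile(both, list(pa, pb))
  expect_true(prof$all_present)
  expect_true(all(prof$counts >= 1))

  only_a <- paste0("aagga", strrep("t", 10))
  prof2 <- motif_presence_profile(only_a, list(pa, pb))
  expect_false(prof2$all_present)

  # a palindromic site counts once per strand
  pal_probs <- matrix(0.01, 4, 4)
  pal_probs[cbind(1:4, c(1, 1, 4, 4))] <- 0.97  # aatt, its own revcomp
  pal <- pwm("pal", pal_probs)
  prof3 <- motif_presence_profile("ggaattgg", pal)
  expect_equal(unname(prof3$counts["pal"]), 2L)

  # random 357-mers essentially never contain a near-exact 10-mer
  # (threshold set so only zero-mismatch windows qualify, matching the
  # 2 * (357 - 10 + 1) * 4^-10 expectation)
  probs10 <- matrix(0.01, 10, 4)
  probs10[cbind(1:10, rep(c(1, 2, 3, 4), length.out = 10))] <- 0.97
  sharp10 <- pwm("s10", probs10, score_threshold = 10)
  rb <- random_baseline(50, 357, seed = 77)
  present <- vapply(rb, function(s) {
    motif_presence_profile(s, sharp10)$all_present
  }, logical(1))
  expect_lt(mean(present), 0.1)
  expect_error(motif_presence_profile("acgt", list()), "empty")
})

test_that("the random baseline is uniform, exact-length and seeded", {
  rb <- random_baseline(300, 357, seed = 5)
  expect_true(all(nchar(rb) == 357))
  at <- vapply(rb, at_content, numeric(1))
  expect_lt(abs(mean(at) - 0.5), 0.01)
  expect_identical(rb, random_baseline(300, 357, seed = 5))
  expect_false(identical(rb[1], random_baseline(1, 357, seed = 6)[1]))
  expect_error(random_baseline(0), "positive")
})

test_that("synthetic wild-type-like fixtures separate from random baseline", {
  co <- make_corpus(synthetic_spec(n_per_family = 10, seed = 303))
  wt_at <- vapply(co$records, function(r) at_content(r$oriv), numeric(1))
  rb <- random_baseline(20, 357, seed = 304)
  rb_at <- vapply(rb, at_content, numeric(1))
  expect_gt(mean(wt_at), mean(rb_at))  # planted AT-rich block

  it_pwms <- Filter(function(p) grepl("iteron", p$name), co$pwms)
  wt_hits <- vapply(co$records[1:10], function(r) {
    sum(motif_presence_profile(r$oriv, it_pwms)$counts)
  }, numeric(1))
  rb_hits <- vapply(rb[1:10], function(s) {
    sum(motif_presence_profile(s, it_pwms)$counts)
  }, numeric(1))
  expect_gt(mean(wt_hits), mean(rb_hits))
})

test_that("PWMs round-trip through the plain-text matrix format", {
  probs <- matrix(0.01, 5, 4); probs[cbind(1:5, c(2, 3, 1, 4, 2))] <- 0.97
  p1 <- pwm("roundtrip", probs, score_threshold = 2.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pwms(list(p1), path)
  back <- read_pwms(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$name, "roundtrip")
  expect_equal(back[[1]]$score_threshold, 2.5)
  expect_equal(back[[1]]$probs, p1$probs, tolerance = 1e-5)
})
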