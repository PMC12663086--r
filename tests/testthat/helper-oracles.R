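# Independent oracles used against the package implementations. These are
# deliberately written from scratch (not via package internals) so that
# implementation and check never share code.

# Pure-R affine-gap DP (scores only, Gotoh with gap runs costing
# open + L * ext, no direct switch between the two gap states).
helper_affine_score <- function(a, b, match = 5, mismatch = -4,
                                open = 10, ext = 0.5) {
  av <- strsplit(tolower(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(tolower(b), "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  js <- 0:m
  M_prev <- c(0, rep(NEG, m))
  X_prev <- rep(NEG, m + 1L)
  Y_prev <- c(NEG, -open - ext * (1:m))
  Y_prev[1L] <- NEG
  M_prev0 <- M_prev
  # row 0 Y via its own recurrence start
  Y_prev <- c(NEG, -open - ext * (1:m))
  for (i in seq_len(n)) {
    X_cur <- pmax(M_prev - open - ext, X_prev - ext)
    X_cur[1L] <- -open - i * ext
    sub <- ifelse(av[i] == bv, match, mismatch)
    best_prev <- pmax(M_prev, pmax(X_prev, Y_prev))
    M_cur <- c(NEG, best_prev[1:m] + sub)
    run <- cummax(M_cur + js * ext)
    Y_cur <- c(NEG, run[1:m] - open - (1:m) * ext)
    M_prev <- M_cur; X_prev <- X_cur; Y_prev <- Y_cur
  }
  max(M_prev[m + 1L], X_prev[m + 1L], Y_prev[m + 1L])
}

# Exponential enumeration over all monotone alignment paths (including
# adjacent opposite-direction gaps), scoring gap runs as open + L * ext.
# Only usable for very short sequences.
helper_enum_score <- function(a, b, match = 5, mismatch = -4,
                              open = 10, ext = 0.5) {
  av <- strsplit(tolower(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(tolower(b), "", fixed = TRUE)[[1L]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(av)) {  # gap in b
      cost <- if (last == "X") ext else open + ext
      best <- max(best, -cost + rec(i + 1L, j, "X"))
    }
    if (j <= length(bv)) {  # gap in a
      cost <- if (last == "Y") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# Naive overlap-aware motif counter over both strands (forward scan plus
# scan of the reverse complement), independent of the package scanner.
helper_count_motifs_both_strands <- function(seq, motifs) {
  comp <- c(a = "t", c = "g", g = "c", t = "a",
            A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]),
                          collapse = "")
  count_one <- function(s, m) {
    s <- toupper(s); m <- toupper(m)
    n <- nchar(s); L <- nchar(m)
    if (L > n) return(0L)
    hits <- 0L
    for (i in 1:(n - L + 1L)) {
      if (substr(s, i, i + L - 1L) == m) hits <- hits + 1L
    }
    hits
  }
  total <- 0L
  for (m in motifs) {
    total <- total + count_one(seq, m) + count_one(rc(seq), m)
  }
  total
}

helper_random_seq <- function(n, alphabet = c("a", "c", "g", "t")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

helper_random_record <- function(id) {
  n_reps <- sample(0:2, 1L)
  species <- sample(c("Escherichia_coli", "Bacillus_subtilis", NA), 1L)
  reps <- vapply(seq_len(n_reps), function(k) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                 sample(3:20, 1L), replace = TRUE), collapse = "")
  }, character(1))
  replicon_record(id, species, reps, helper_random_seq(sample(4:60, 1L)))
}
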