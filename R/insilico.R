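#' AT content of a nucleotide sequence
#'
#' Fraction of positions that are `a` or `t` (case-insensitive). Natural
#' oriVs are AT-rich relative to random sequence, which eases strand
#' opening at replication initiation.
#'
#' @param seq Non-empty ACGT string.
#' @return Fraction in \[0, 1\].
#' @examples
#' at_content("atgc")  # 0.5
#' @export
at_content <- function(seq) {
  if (!nzchar(seq)) stop("at_content: empty sequence")
  chars <- strsplit(tolower(seq), "", fixed = TRUE)[[1L]]
  .check_alphabet(paste(chars, collapse = ""), NUC_ALPHABET, "input", "seq")
  mean(chars %in% c("a", "t"))
}

#' Folding energy of windows along a sequence
#'
#' Slides a window of `window` bases at step 1 (0-based half-open windows)
#' and applies a folding engine to each window, returning the per-window
#' values and their mean. The built-in engine is a Nussinov
#' maximum-base-pairing stand-in (`-1` per Watson-Crick pair, minimum
#' hairpin loop 3): always non-positive, zero for homopolymers, and makes
#' no claim of thermodynamic accuracy. Any function mapping a nucleotide
#' string to a numeric value can be plugged in (e.g. a wrapper around an
#' external thermodynamic folder).
#'
#' @param seq Nucleotide string of length >= `window`.
#' @param window Window size in bases (default 100).
#' @param engine Function(character) -> numeric; default
#'   [nussinov_energy()].
#' @return List with `values` (length `nchar(seq) - window + 1`) and
#'   `mean`.
#' @export
windowed_mfe <- function(seq, window = 100L, engine = nussinov_energy) {
  seq <- tolower(seq)
  n <- nchar(seq)
  if (n < window)
    stop("sequence length ", n, " is shorter than the window (", window, ")")
  starts <- 1:(n - window + 1L)
  vals <- vapply(starts, function(i) {
    engine(substr(seq, i, i + window - 1L))
  }, numeric(1))
  list(values = vals, mean = mean(vals))
}

#' Nussinov maximum-pairing stand-in folding energy
#'
#' Negated count of the maximum number of non-crossing Watson-Crick pairs
#' with a minimum hairpin loop of 3 unpaired bases.
#'
#' @param seq Nucleotide string.
#' @return Non-positive numeric.
#' @export
nussinov_energy <- function(seq) {
  .nussinov_energy(tolower(seq))
}

#' Construct a position weight matrix
#'
#' The scoring matrix holds per-position log-likelihood ratios
#' `log(p_base / background)`; scanning sums them over the motif window
#' and a hit is any window scoring strictly above `score_threshold`
#' (default 1.0, the conventional log-likelihood cutoff).
#'
#' @param name Motif name.
#' @param probs L x 4 matrix of per-position base probabilities, columns
#'   in order A, C, G, T; each row sums to 1.
#' @param background Length-4 background probabilities (default uniform).
#' @param score_threshold Hit threshold on the summed log-likelihood ratio.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4),
                score_threshold = 1.0) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 4L) stop("pwm must span at least 4 positions")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("each pwm row must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  colnames(probs) <- c("A", "C", "G", "T")
  mat <- log(sweep(probs, 2L, background, "/"))
  structure(list(name = name, probs = probs, mat = mat,
                 background = background,
                 score_threshold = score_threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  consensus <- c("a", "c", "g", "t")[max.col(x$probs)]
  cat(sprintf("pwm '%s': %d positions, threshold %.2f, consensus %s\n",
              x$name, nrow(x$mat), x$score_threshold,
              paste(consensus, collapse = "")))
  invisible(x)
}

# Max attainable score (sum of per-row maxima of the weight matrix).
pwm_max_score <- function(p) sum(apply(p$mat, 1L, max))

# Reverse-complement a PWM: reverse position order, swap A<->T and C<->G.
.pwm_revcomp_mat <- function(mat) {
  mat[rev(seq_len(nrow(mat))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Scan a sequence with PWMs on both strands
#'
#' Every offset on both strands is scored as the sum of per-position
#' weights; hits are windows with score strictly greater than the PWM's
#' threshold. Overlapping hits are all reported. Minus-strand hits are
#' reported in forward coordinates (the window whose reverse complement
#' matches). A PWM longer than the sequence yields zero hits.
#'
#' @param seq Nucleotide string.
#' @param pwms A `pwm` or list of `pwm` objects.
#' @return Data frame with columns `motif`, `start` (0-based), `end`
#'   (half-open), `strand` (`+`/`-`), `score`.
#' @export
scan_pwm <- function(seq, pwms) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!length(pwms)) stop("scan_pwm: empty PWM list")
  seq <- tolower(seq)
  .check_alphabet(seq, NUC_ALPHABET, "input", "seq")
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]], NUC_ALPHABET)
  n <- length(code)
  out <- list()
  for (p in pwms) {
    L <- nrow(p$mat)
    if (L > n) next
    for (strand in c("+", "-")) {
      mat <- if (strand == "+") p$mat else .pwm_revcomp_mat(p$mat)
      scores <- numeric(n - L + 1L)
      for (l in seq_len(L)) {
        scores <- scores + mat[l, code[l:(n - L + l)]]
      }
      hit <- which(scores > p$score_threshold)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          motif = p$name, start = hit - 1L, end = hit - 1L + L,
          strand = strand, score = scores[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif, res$strand), , drop = FALSE]
}

#' Per-motif hit counts and joint presence
#'
#' Counts [scan_pwm()] hits per motif (strand-summed, so a palindromic
#' site counts once per strand) and reports whether every motif has at
#' least one hit — the "all motifs present" filter used when triaging
#' generated origins.
#'
#' @inheritParams scan_pwm
#' @return List with `counts` (named integer vector per motif) and
#'   `all_present` (logical).
#' @export
motif_presence_profile <- function(seq, pwms) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!length(pwms)) stop("motif_presence_profile: empty PWM list")
  hits <- scan_pwm(seq, pwms)
  nm <- vapply(pwms, `[[`, character(1), "name")
  counts <- setNames(integer(length(nm)), nm)
  if (nrow(hits)) {
    tab <- table(hits$motif)
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, all_present = all(counts >= 1L))
}

#' Uniform-random nucleotide baseline sequences
#'
#' I.i.d. uniform ACGT strings used as the null comparison for AT content,
#' folding energy and motif counts; the default length 357 is the median
#' oriV length of the reference training corpus.
#'
#' @param n Number of sequences (default 1000).
#' @param length Sequence length (default 357).
#' @param seed Seed.
#' @return Character vector of lowercase sequences, named `random_0001`...
#' @export
random_baseline <- function(n = 1000L, length = 357L, seed = 1L) {
  if (n < 1L || length < 1L) stop("n and length must be positive")
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(NUC_ALPHABET, length, replace = TRUE), collapse = "")
  }, character(1))
  setNames(seqs, sprintf("random_%04d", seq_len(n)))
}

#' Read / write PWM files
#'
#' Minimal plain-text matrix format: a `>name [threshold]` line followed
#' by L rows of 4 base probabilities in order A C G T; several PWMs may
#' be concatenated. The reader converts probabilities to log-likelihood
#' ratios against the given background.
#'
#' @param path File path.
#' @param background Background probabilities used for the conversion.
#' @return `read_pwms`: list of `pwm` objects.
#' @export
read_pwms <- function(path, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no PWM records in ", path)
  bounds <- c(heads, length(lines) + 1L)
  lapply(seq_along(heads), function(i) {
    fields <- strsplit(sub("^>", "", lines[heads[i]]), "\\s+")[[1L]]
    rows <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    probs <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    thr <- if (length(fields) > 1L) as.numeric(fields[2L]) else 1.0
    pwm(fields[1L], probs, background = background, score_threshold = thr)
  })
}

#' @rdname read_pwms
#' @param pwms List of `pwm` objects.
#' @export
write_pwms <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %.6g", p$name, p$score_threshold), con)
    write.table(format(p$probs, digits = 6), con, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write PWM hits as BED-like TSV
#'
#' Columns: seq_id, start, end (0-based half-open), motif, score, strand.
#'
#' @param hits Data frame from [scan_pwm()].
#' @param seq_id Sequence identifier for the first column.
#' @param path File path.
#' @export
write_hits_bed <- function(hits, seq_id, path) {
  bed <- data.frame(seq_id = seq_id, start = hits$start, end = hits$end,
                    motif = hits$motif, score = hits$score,
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
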