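#' Affine-gap global alignment of two nucleotide sequences
#'
#' Needleman-Wunsch / Gotoh global alignment with affine gap penalties and
#' EMBOSS-style defaults: match +5, mismatch -4, and a gap run of length L
#' costing `gap_open + L * gap_extend`. End gaps are penalized (true global
#' alignment). The traceback is deterministic with tie order
#' diagonal > up > left, where "up" consumes a character of `a`.
#'
#' Edit counts describe the edits transforming `b` into `a`: `n_ins` counts
#' alignment columns where `a` has a base over a gap in `b`, `n_del` the
#' converse, `n_sub` mismatched base columns. `identity_pct` is the fraction
#' of alignment columns with matching bases (gaps count in the denominator).
#'
#' @param a,b Non-empty nucleotide strings (case-insensitive; compared
#'   after lowercasing).
#' @param gap_open,gap_extend,match,mismatch Scoring parameters.
#' @return An object of class `alignment_result`: list with `aligned_a`,
#'   `aligned_b`, `score`, `identity_pct` (fraction in \[0, 1\]), `n_sub`,
#'   `n_ins`, `n_del`, `length` (alignment columns).
#' @examples
#' global_align("acgt", "aagt")
#' @export
global_align <- function(a, b, gap_open = 10.0, gap_extend = 0.5,
                         match = 5.0, mismatch = -4.0) {
  if (!nzchar(a) || !nzchar(b)) stop("global_align: empty input sequence")
  raw <- .gotoh_align(tolower(a), tolower(b), match, mismatch,
                      gap_open, gap_extend)
  ca <- strsplit(raw$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(raw$aligned_b, "", fixed = TRUE)[[1L]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  n_match <- sum(!gap_a & !gap_b & ca == cb)
  structure(
    list(aligned_a = raw$aligned_a,
         aligned_b = raw$aligned_b,
         score = raw$score,
         identity_pct = n_match / length(ca),
         n_sub = sum(!gap_a & !gap_b & ca != cb),
         n_ins = sum(gap_b),
         n_del = sum(gap_a),
         length = length(ca)),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment_result: score %.1f, identity %.1f%%, %d sub / %d ins / %d del over %d columns\n",
    x$score, 100 * x$identity_pct, x$n_sub, x$n_ins, x$n_del, x$length))
  invisible(x)
}

#' Find the closest wild-type reference for a query sequence
#'
#' Candidate references are ranked by the number of k-mers shared with the
#' query (a BLAST-like prefilter with no external binary); the top candidate
#' is then aligned globally with [global_align()] and returned. If no
#' reference shares a single k-mer with the query (or the query is shorter
#' than `k`), the slow fallback path aligns the query against every
#' reference and returns the best score.
#'
#' @param query Nucleotide string.
#' @param references Named character vector or named list, id -> sequence.
#' @param k K-mer size for the prefilter (default 11).
#' @param ... Passed to [global_align()].
#' @return List with `ref_id` and `alignment` (an `alignment_result`).
#' @export
closest_wildtype <- function(query, references, k = 11L, ...) {
  refs <- unlist(references)
  if (!length(refs)) stop("closest_wildtype: empty reference set")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("closest_wildtype: references must be named")
  query <- tolower(query)
  shared <- if (nchar(query) >= k) {
    qk <- unique(.kmers(query, k))
    vapply(refs, function(r) {
      if (nchar(r) < k) 0L else sum(unique(.kmers(tolower(r), k)) %in% qk)
    }, integer(1))
  } else {
    setNames(integer(length(refs)), names(refs))
  }
  if (max(shared) > 0L) {
    best <- names(refs)[which.max(shared)]  # first max: deterministic
    list(ref_id = best, alignment = global_align(query, refs[[best]], ...))
  } else {
    alns <- lapply(refs, function(r) global_align(query, r, ...))
    scores <- vapply(alns, `[[`, numeric(1), "score")
    best <- names(refs)[which.max(scores)]
    list(ref_id = best, alignment = alns[[best]])
  }
}

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}
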