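#' Specification of a matched random mutant
#'
#' Edit counts extracted from an alignment of a generated sequence to its
#' closest wild type; applying them at random positions of the wild type
#' yields the matched control.
#'
#' @param n_sub,n_ins,n_del Non-negative edit counts.
#' @param seed Integer seed.
#' @return A `mutant_spec` list.
#' @export
mutant_spec <- function(n_sub = 0L, n_ins = 0L, n_del = 0L, seed = 1L) {
  if (n_sub < 0 || n_ins < 0 || n_del < 0) stop("edit counts must be >= 0")
  structure(list(n_sub = as.integer(n_sub), n_ins = as.integer(n_ins),
                 n_del = as.integer(n_del), seed = as.integer(seed)),
            class = "mutant_spec")
}

#' @rdname mutant_spec
#' @param alignment An `alignment_result` (edits of b -> a).
#' @param seed Seed for the mutant draw.
#' @export
mutant_spec_from_alignment <- function(alignment, seed = 1L) {
  stopifnot(inherits(alignment, "alignment_result"))
  mutant_spec(alignment$n_sub, alignment$n_ins, alignment$n_del, seed)
}

#' Apply a matched number of random mutations to a wild-type sequence
#'
#' Exactly `n_del` deletions, then `n_ins` random-base insertions, then
#' `n_sub` substitutions to a different base, at seeded-random distinct
#' positions (deletions applied first, then insertions, then
#' substitutions, each on the current coordinates). The output length is
#' `len(wt) + n_ins - n_del`. Because mutations interact, re-aligning the
#' mutant to the wild type may recover slightly different edit counts
#' than the spec — matched controls are matched in edit numbers, not in
#' alignment.
#'
#' @param wt Lowercase nucleotide string.
#' @param spec A [mutant_spec()].
#' @return Mutant sequence string.
#' @export
apply_matched_mutations <- function(wt, spec) {
  stopifnot(inherits(spec, "mutant_spec"))
  wt <- tolower(wt)
  .check_alphabet(wt, NUC_ALPHABET, "wt", "sequence")
  if (spec$n_del > nchar(wt))
    stop("n_del exceeds the wild-type length")
  if (spec$n_sub > nchar(wt) - spec$n_del)
    stop("n_sub exceeds the post-deletion length")
  old <- .save_rng(spec$seed)
  on.exit(.restore_rng(old))
  chars <- strsplit(wt, "", fixed = TRUE)[[1L]]
  if (spec$n_del > 0L) {
    chars <- chars[-sample.int(length(chars), spec$n_del)]
  }
  if (spec$n_ins > 0L) {
    # insertion slots 0..n (before, between, after); distinct slots
    slots <- sort(sample.int(length(chars) + 1L, spec$n_ins,
                             replace = FALSE) - 1L, decreasing = TRUE)
    for (s in slots) {
      chars <- append(chars, sample(NUC_ALPHABET, 1L), after = s)
    }
  }
  if (spec$n_sub > 0L) {
    at <- sample.int(length(chars), spec$n_sub)
    for (i in at) {
      chars[i] <- sample(setdiff(NUC_ALPHABET, chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Remove forbidden motifs from a wild type by minimal random substitutions
#'
#' The wild-type-derived control for constraint-guided generation: while
#' any forbidden-motif occurrence remains, one nucleotide of the leftmost
#' occurrence is chosen at random and substituted with a random different
#' nucleotide; iterated until the sequence is motif-free on both strands
#' (the motif set is reverse-complement-closed). Only substitutions are
#' used, so length is preserved.
#'
#' @param wt Lowercase nucleotide string.
#' @param forbidden An `expanded_motif_set`.
#' @param seed Seed.
#' @param max_iters Iteration bound before giving up.
#' @return The motif-free sequence with attribute `n_substitutions`.
#' @export
strip_restriction_sites_minimal <- function(wt, forbidden, seed = 1L,
                                            max_iters = 10000L) {
  seq <- tolower(wt)
  .check_alphabet(seq, NUC_ALPHABET, "wt", "sequence")
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  n_subs <- 0L
  iters <- 0L
  while (!is.null(occ <- .first_motif_occurrence(seq, forbidden))) {
    iters <- iters + 1L
    if (iters > max_iters)
      stop("strip_restriction_sites_minimal: max_iters exceeded")
    pos <- occ$start + sample.int(occ$len, 1L) - 1L
    alt <- sample(setdiff(NUC_ALPHABET, substr(seq, pos, pos)), 1L)
    substr(seq, pos, pos) <- alt
    n_subs <- n_subs + 1L
  }
  structure(seq, n_substitutions = n_subs)
}
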