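IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Expand IUPAC motif patterns to a reverse-complement-closed motif set
#'
#' Every degenerate position is expanded to its full set of concrete
#' nucleotides (Cartesian product), the reverse complement of every
#' expanded sequence is added, and duplicates are collapsed. The result is
#' the concrete forbidden-motif set used by constrained decoding: because
#' it is closed under reverse complement, scanning only the forward strand
#' of a sequence covers both strands.
#'
#' Patterns shorter than three nucleotides, or with more than five
#' degenerate positions, are rejected (the fixture filter applied to the
#' restriction-site list).
#'
#' @param patterns Character vector of IUPAC nucleotide patterns.
#' @return An `expanded_motif_set`: uppercase character vector of concrete
#'   ACGT motifs, sorted, closed under reverse complement.
#' @examples
#' expand_motifs("CCWGG")   # CCAGG + CCTGG
#' @export
expand_motifs <- function(patterns) {
  patterns <- toupper(patterns)
  out <- character(0)
  for (p in patterns) {
    chars <- strsplit(p, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% names(IUPAC_MAP))
    if (length(bad))
      stop("invalid IUPAC character '", chars[bad[1L]], "' in pattern ", p)
    if (length(chars) < 3L)
      stop("pattern '", p, "' is shorter than three nucleotides")
    if (sum(!chars %in% c("A", "C", "G", "T")) > 5L)
      stop("pattern '", p, "' has more than five degenerate positions")
    grid <- expand.grid(IUPAC_MAP[chars], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    out <- c(out, do.call(paste0, grid))
  }
  out <- unique(c(out, vapply(out, .revcomp_upper, character(1))))
  structure(sort(out), class = "expanded_motif_set")
}

.revcomp_upper <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

#' Read a motif list file
#'
#' Plain text, one IUPAC pattern per line; `#` starts a comment. The
#' twelve-motif restriction-site fixture ships as
#' `system.file("extdata", "restriction_motifs.txt", package = "oriforge")`.
#'
#' @param path File path.
#' @return Character vector of patterns (not yet expanded).
#' @export
read_motif_list <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  toupper(x[nzchar(x)])
}

# Overlap-aware count of concrete motif occurrences on the forward strand
# of `seq` (case-insensitive). With a reverse-complement-closed motif set
# this covers both strands.
count_motif_occurrences <- function(seq, motifs) {
  S <- toupper(seq)
  n <- nchar(S)
  total <- 0L
  for (m in motifs) {
    L <- nchar(m)
    if (L > n) next
    starts <- 1:(n - L + 1L)
    total <- total + sum(substring(S, starts, starts + L - 1L) == m)
  }
  total
}

# First (leftmost) occurrence of any motif; list(start, len) 1-based, or NULL.
.first_motif_occurrence <- function(seq, motifs) {
  S <- toupper(seq)
  n <- nchar(S)
  best <- NULL
  for (m in motifs) {
    L <- nchar(m)
    if (L > n) next
    starts <- which(substring(S, 1:(n - L + 1L), L:n) == m)
    if (length(starts) && (is.null(best) || starts[1L] < best$start))
      best <- list(start = starts[1L], len = L)
  }
  best
}

#' Generate sequences under forbidden-motif constraints by beam search
#'
#' Deterministic beam search over nucleotide continuations of the prompt.
#' Before a candidate extension is scored, the uppercase suffix window of
#' its oriV (spanning the prompt/generation boundary) is checked against
#' the forbidden set and matching hypotheses are pruned, so every returned
#' sequence contains zero forbidden-motif occurrences; both strands are
#' covered because the set is reverse-complement-closed. Beams are ranked
#' by total log-likelihood; ties break by token id, ascending.
#'
#' @param model An `ori_model`.
#' @param vocab The model's `ori_vocabulary`.
#' @param config A [generation_config()] with `mode = "beam"` and a
#'   non-empty `forbidden` set. The nucleotide portion of the prompt must
#'   itself be motif-free (repair it first with [infill_repair()]).
#' @return List of up to `n_beams` [replicon_record()]s, ranked by total
#'   log-likelihood (attributes `tokens`, `loglik`, `truncated`).
#' @export
generate_constrained <- function(model, vocab, config) {
  stopifnot(inherits(config, "generation_config"))
  if (config$mode != "beam")
    stop("generate_constrained requires mode = 'beam'")
  forbidden <- config$forbidden
  if (is.null(forbidden) || !length(forbidden))
    stop("empty forbidden set: use generate() for unconstrained sampling")
  g <- .grammar_init(vocab)
  .check_prompt(config$prompt, g)
  nuc_ids <- g$nuc
  eos <- g$sp[["eos"]]

  prompt_nt <- .prompt_nt_tail(config$prompt, vocab)
  if (count_motif_occurrences(prompt_nt, forbidden) > 0L)
    stop("the prompt's nucleotide seed already contains a forbidden motif; ",
         "repair it with infill_repair() before constrained generation")
  wlen <- max(nchar(forbidden)) - 1L
  win0 <- toupper(substr(prompt_nt, max(1L, nchar(prompt_nt) - wlen + 1L),
                         nchar(prompt_nt)))

  state0 <- .decoder_init(model, config$max_len)
  ids0 <- config$prompt
  for (id in ids0) {
    st <- .decoder_step(model, state0, id)
    state0 <- st$state
  }
  beams <- list(list(ids = ids0, logp = 0, state = state0,
                     logits = st$logits,
                     parse = .grammar_state_of(ids0, g), window = win0))
  done <- list()

  while (length(beams) && length(done) < config$n_beams) {
    cand <- list()
    for (bi in seq_along(beams)) {
      b <- beams[[bi]]
      allowed <- .grammar_allowed(b$parse, g)
      lg <- b$logits[allowed + 1L]
      lp <- lg - (max(lg) + log(sum(exp(lg - max(lg)))))  # log-softmax
      for (j in seq_along(allowed)) {
        id <- allowed[j]
        if (id %in% nuc_ids) {
          ch <- toupper(vocab$tokens[id + 1L])
          w <- paste0(b$window, ch)
          if (any(endsWith(w, forbidden))) next  # pruned before scoring
          cand[[length(cand) + 1L]] <- list(bi = bi, id = id,
                                            logp = b$logp + lp[j],
                                            window = .clip_window(w, wlen))
        } else {
          cand[[length(cand) + 1L]] <- list(bi = bi, id = id,
                                            logp = b$logp + lp[j],
                                            window = b$window)
        }
      }
    }
    if (!length(cand)) {
      if (length(done)) break
      stop("constrained generation infeasible: all beams were pruned ",
           "before reaching <eos>")
    }
    lps <- vapply(cand, `[[`, numeric(1), "logp")
    tid <- vapply(cand, `[[`, numeric(1), "id")
    keep <- head(order(-lps, tid), config$n_beams)
    new_beams <- list()
    for (ci in keep) {
      cn <- cand[[ci]]
      b <- beams[[cn$bi]]
      ids <- c(b$ids, cn$id)
      if (cn$id == eos) {
        done[[length(done) + 1L]] <- list(ids = ids, logp = cn$logp,
                                          truncated = FALSE)
        next
      }
      if (length(ids) >= config$max_len) {
        done[[length(done) + 1L]] <- list(ids = ids, logp = cn$logp,
                                          truncated = TRUE)
        next
      }
      st <- .decoder_step(model, b$state, cn$id)
      new_beams[[length(new_beams) + 1L]] <-
        list(ids = ids, logp = cn$logp, state = st$state, logits = st$logits,
             parse = .grammar_next(b$parse, cn$id, g), window = cn$window)
    }
    beams <- new_beams
  }

  if (!length(done))
    stop("constrained generation infeasible: all beams were pruned ",
         "before reaching <eos>")
  lps <- vapply(done, `[[`, numeric(1), "logp")
  done <- done[order(-lps)]
  done <- done[seq_len(min(config$n_beams, length(done)))]
  lapply(seq_along(done), function(i) {
    d <- done[[i]]
    rec <- decode_tokens(new_token_sequence(d$ids), vocab,
                         record_id = sprintf("gen_beam_%03d", i),
                         allow_truncated = TRUE)
    attr(rec, "tokens") <- new_token_sequence(d$ids)
    attr(rec, "loglik") <- d$logp
    attr(rec, "truncated") <- d$truncated
    rec
  })
}

.clip_window <- function(w, wlen) {
  if (nchar(w) > wlen) substr(w, nchar(w) - wlen + 1L, nchar(w)) else w
}

.prompt_nt_tail <- function(prompt, vocab) {
  cls <- unname(vocab$class_of[vocab$tokens[as.integer(prompt) + 1L]])
  nt <- vocab$tokens[as.integer(prompt) + 1L][cls == "NUCLEOTIDE"]
  paste(nt, collapse = "")
}

#' Repair a sequence by model-guided single-base infill substitutions
#'
#' While any forbidden-motif occurrence remains: at the leftmost
#' occurrence, every single-base substitution inside the occurrence window
#' that removes it is scored by the autoregressive log-likelihood of the
#' full sequence under the model, and the highest-likelihood one is
#' applied. Terminates with a motif-free sequence (bounded by
#' `3 * nchar(sequence)` attempts) or raises an error if no substitution
#' can clear an occurrence within the bound.
#'
#' @param sequence Lowercase nucleotide string.
#' @param forbidden An `expanded_motif_set`.
#' @param model An `ori_model`.
#' @param vocab The model's `ori_vocabulary`.
#' @param species Optional species label used as scoring context
#'   (`NA` = unknown-species token).
#' @return The repaired lowercase sequence, with attribute `n_edits`.
#' @export
infill_repair <- function(sequence, forbidden, model, vocab,
                          species = NA_character_) {
  seq <- tolower(sequence)
  .check_alphabet(seq, NUC_ALPHABET, "infill", "sequence")
  n_edits <- 0L
  max_iters <- 3L * nchar(seq)
  iters <- 0L
  while (!is.null(occ <- .first_motif_occurrence(seq, forbidden))) {
    iters <- iters + 1L
    if (iters > max_iters)
      stop("infill_repair: retry bound exceeded with occurrences remaining")
    best <- NULL
    for (pos in occ$start:(occ$start + occ$len - 1L)) {
      for (alt in setdiff(NUC_ALPHABET, substr(seq, pos, pos))) {
        cand <- seq
        substr(cand, pos, pos) <- alt
        # must actually remove this occurrence (no motif covering the window)
        region_start <- max(1L, occ$start - max(nchar(forbidden)) + 1L)
        region_end <- min(nchar(cand), occ$start + occ$len - 1L +
                            max(nchar(forbidden)) - 1L)
        still <- .first_motif_occurrence(substr(cand, region_start,
                                                region_end), forbidden)
        covers <- !is.null(still) &&
          (still$start + region_start - 1L) <= (occ$start + occ$len - 1L) &&
          (still$start + region_start - 1L + still$len - 1L) >= occ$start
        if (covers) next
        ll <- .sequence_loglik(model, .infill_ids(cand, vocab, species))
        if (is.null(best) || ll > best$ll)
          best <- list(seq = cand, ll = ll)
      }
    }
    if (is.null(best))
      stop("infill_repair: no single substitution clears the occurrence at ",
           occ$start - 1L, " (0-based)")
    if (best$seq != seq) n_edits <- n_edits + 1L
    seq <- best$seq
  }
  structure(seq, n_edits = n_edits)
}

.infill_ids <- function(seq, vocab, species) {
  sp <- special_ids(vocab)
  species_tok <- if (is.na(species)) sp[["unk_species"]] else {
    if (!species %in% names(vocab$token_to_id)) sp[["unk_species"]]
    else vocab$token_to_id[[species]]
  }
  c(sp[["bos"]], species_tok, .chars_to_ids(seq, vocab, "infill"),
    sp[["eos"]])
}
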