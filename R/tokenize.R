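#' Encode a replicon record as a token sequence
#'
#' Layout: `<bos>`, species token (or `<unk_species>`), the Rep protein
#' amino acids with `<sep>` between consecutive Reps, the oriV nucleotides,
#' `<eos>`. Encoding and [decode_tokens()] are exact inverses on valid
#' records.
#'
#' @param record A [replicon_record()].
#' @param vocab An `ori_vocabulary` containing every symbol of the record
#'   (an unknown species label maps to `<unk_species>` only if it is absent
#'   from the vocabulary's species tokens).
#' @param context_len Maximum admissible token count; longer records are
#'   rejected (never truncated) with the measured length in the error.
#' @return A `token_sequence`: integer vector of 0-based token ids with
#'   attribute `record_id`.
#' @examples
#' recs <- list(replicon_record("r1", "Ecoli", character(), "acgt"))
#' v <- build_vocabulary(recs)
#' encode_replicon(recs[[1]], v)
#' @export
encode_replicon <- function(record, vocab, context_len = 1500L) {
  validate_replicon_record(record)
  sp <- special_ids(vocab)
  species_tok <- if (is_unknown_species(record)) {
    sp[["unk_species"]]
  } else if (record$host_species %in% names(vocab$token_to_id) &&
             vocab$class_of[[record$host_species]] == "SPECIES") {
    vocab$token_to_id[[record$host_species]]
  } else {
    sp[["unk_species"]]
  }
  rep_ids <- integer(0)
  for (k in seq_along(record$rep_proteins)) {
    if (k > 1L) rep_ids <- c(rep_ids, sp[["sep"]])
    rep_ids <- c(rep_ids, .chars_to_ids(record$rep_proteins[k], vocab,
                                        record$record_id))
  }
  ids <- c(sp[["bos"]], species_tok, rep_ids,
           .chars_to_ids(record$oriv, vocab, record$record_id), sp[["eos"]])
  if (length(ids) > context_len)
    stop("record '", record$record_id, "' encodes to ", length(ids),
         " tokens, exceeding the context window of ", context_len)
  new_token_sequence(unname(ids), record$record_id)
}

new_token_sequence <- function(ids, record_id = NA_character_) {
  structure(as.integer(ids), record_id = record_id, class = "token_sequence")
}

.chars_to_ids <- function(s, vocab, record_id) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  miss <- which(!chars %in% names(vocab$token_to_id))
  if (length(miss))
    stop("record '", record_id, "': symbol '", chars[miss[1L]],
         "' at offset ", miss[1L] - 1L, " is not in the vocabulary")
  unname(vocab$token_to_id[chars])
}

#' Decode a token sequence back to a replicon record
#'
#' Inverse of [encode_replicon()] on its image. The layout grammar is
#' enforced strictly: `<bos>`, a species-class token or `<unk_species>`,
#' an optional Rep block (amino acids with `<sep>` separators, each Rep
#' non-empty), at least one nucleotide, then `<eos>`. Malformed input
#' raises a parse error naming the 0-based offending position.
#'
#' @param tokens A `token_sequence` or integer vector of 0-based ids.
#' @param vocab The `ori_vocabulary` used for encoding.
#' @param record_id Identifier given to the decoded record.
#' @param allow_truncated If `TRUE`, a sequence that ends inside the oriV
#'   region without `<eos>` (e.g. generation stopped at the length cap) is
#'   accepted. Default `FALSE`.
#' @return A [replicon_record()].
#' @export
decode_tokens <- function(tokens, vocab, record_id = NULL,
                          allow_truncated = FALSE) {
  ids <- as.integer(tokens)
  record_id <- record_id %||% (attr(tokens, "record_id") %||% "decoded")
  sp <- special_ids(vocab)
  n <- length(ids)
  fail <- function(pos, why) {
    stop("token parse error at position ", pos - 1L, " (0-based): ", why)
  }
  if (n < 4L) fail(n, "sequence too short for <bos>, species, oriv, <eos>")
  if (any(ids < 0L | ids >= vocab_size(vocab))) {
    bad <- which(ids < 0L | ids >= vocab_size(vocab))[1L]
    fail(bad, "token id out of range")
  }
  tok <- vocab$tokens[ids + 1L]
  cls <- unname(vocab$class_of[tok])
  if (ids[1L] != sp[["bos"]]) fail(1L, "expected <bos>")
  if (!(cls[2L] == "SPECIES" || ids[2L] == sp[["unk_species"]]))
    fail(2L, "expected a species token or <unk_species>")
  host <- if (ids[2L] == sp[["unk_species"]]) NA_character_ else tok[2L]

  i <- 3L
  reps <- character(0)
  cur <- character(0)
  while (i <= n && (cls[i] == "AMINO_ACID" || ids[i] == sp[["sep"]])) {
    if (ids[i] == sp[["sep"]]) {
      if (!length(cur)) fail(i, "<sep> with no preceding Rep tokens")
      reps <- c(reps, paste(cur, collapse = ""))
      cur <- character(0)
    } else {
      cur <- c(cur, tok[i])
    }
    i <- i + 1L
  }
  if (length(reps) && !length(cur)) fail(i, "<sep> with no following Rep tokens")
  if (length(cur)) reps <- c(reps, paste(cur, collapse = ""))

  j <- i
  while (j <= n && cls[j] == "NUCLEOTIDE") j <- j + 1L
  if (j == i) fail(i, "expected at least one oriV nucleotide")
  oriv <- paste(tok[i:(j - 1L)], collapse = "")
  if (j > n) {
    if (!allow_truncated) fail(n, "missing <eos>")
  } else {
    if (ids[j] != sp[["eos"]]) fail(j, "expected <eos> after the oriV")
    if (j != n) fail(j + 1L, "trailing tokens after <eos>")
  }
  replicon_record(record_id, host, reps, oriv)
}

#' Build a generation prompt as a partial token sequence
#'
#' Assembles the leading portion of the token layout used to condition
#' generation: `<bos>`, then optionally a species token, Rep protein(s)
#' and/or the first nucleotides of an oriV seed. The prompt is a valid
#' prefix of the layout grammar.
#'
#' @param vocab An `ori_vocabulary`.
#' @param species Species label, `NA` for `<unk_species>`, or `NULL` to
#'   let the model choose the species (empty conditioning).
#' @param rep_proteins Character vector of amino-acid sequences (requires a
#'   species, possibly unknown).
#' @param oriv_seed Lowercase nucleotide seed (e.g. the first 20 nt of a
#'   known origin), or `NULL`.
#' @return A `token_sequence` prompt.
#' @export
make_prompt <- function(vocab, species = NULL, rep_proteins = character(),
                        oriv_seed = NULL) {
  sp <- special_ids(vocab)
  ids <- sp[["bos"]]
  if (is.null(species) && (length(rep_proteins) || !is.null(oriv_seed)))
    stop("rep_proteins/oriv_seed conditioning requires a species token ",
         "(use species = NA for <unk_species>)")
  if (!is.null(species)) {
    ids <- c(ids, if (is.na(species)) sp[["unk_species"]] else {
      if (!species %in% names(vocab$token_to_id) ||
          vocab$class_of[[species]] != "SPECIES")
        stop("unknown species label: ", species)
      vocab$token_to_id[[species]]
    })
  }
  for (k in seq_along(rep_proteins)) {
    if (k > 1L) ids <- c(ids, sp[["sep"]])
    ids <- c(ids, .chars_to_ids(rep_proteins[k], vocab, "prompt"))
  }
  if (!is.null(oriv_seed) && nchar(oriv_seed))
    ids <- c(ids, .chars_to_ids(oriv_seed, vocab, "prompt"))
  new_token_sequence(unname(ids), "prompt")
}

# oriV token positions (1-based indices into ids) of an encoded record:
# the maximal trailing run of NUCLEOTIDE-class tokens before <eos>.
oriv_token_positions <- function(ids, vocab) {
  ids <- as.integer(ids)
  cls <- unname(vocab$class_of[vocab$tokens[ids + 1L]])
  n <- length(ids)
  stop_at <- if (ids[n] == special_ids(vocab)[["eos"]]) n - 1L else n
  i <- stop_at
  while (i >= 1L && cls[i] == "NUCLEOTIDE") i <- i - 1L
  if (i == stop_at) integer(0) else (i + 1L):stop_at
}
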