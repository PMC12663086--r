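#' Build the token vocabulary from a set of replicon records
#'
#' The vocabulary is a bijective token-to-id map over four disjoint token
#' classes: the five special tokens (`<pad>`, `<bos>`, `<eos>`, `<sep>`,
#' `<unk_species>`), one token per distinct host species label observed in
#' the records, the 20 amino-acid letters, and the 4 lowercase nucleotides.
#' Ids are contiguous from 0 in the fixed, deterministic order
#' specials < sorted species < amino acids < nucleotides, so rebuilding from
#' a permuted record list yields an identical map.
#'
#' @param records Non-empty list of [replicon_record()] objects.
#' @return An object of class `ori_vocabulary` with elements `tokens`
#'   (character vector in id order, id = position - 1), `token_to_id`
#'   (named integer vector of 0-based ids) and `class_of` (named character
#'   vector over `SPECIAL`, `SPECIES`, `AMINO_ACID`, `NUCLEOTIDE`).
#' @examples
#' recs <- list(replicon_record("r1", "Escherichia_coli", character(), "acgt"))
#' v <- build_vocabulary(recs)
#' vocab_size(v)
#' @export
build_vocabulary <- function(records) {
  if (!length(records)) stop("cannot build a vocabulary from an empty record list")
  for (r in records) validate_replicon_record(r)
  species <- vapply(records, function(r) r$host_species, character(1))
  species <- sort(unique(species[!is.na(species) & species != ""]))
  clash <- intersect(species, c(SPECIAL_TOKENS, AA_ALPHABET, NUC_ALPHABET))
  if (length(clash))
    stop("species label collides with a reserved token: ", clash[1L])
  tokens <- c(SPECIAL_TOKENS, species, AA_ALPHABET, NUC_ALPHABET)
  class_of <- c(rep("SPECIAL", length(SPECIAL_TOKENS)),
                rep("SPECIES", length(species)),
                rep("AMINO_ACID", length(AA_ALPHABET)),
                rep("NUCLEOTIDE", length(NUC_ALPHABET)))
  new_vocabulary(tokens, class_of)
}

new_vocabulary <- function(tokens, class_of) {
  stopifnot(length(tokens) == length(class_of), !anyDuplicated(tokens))
  structure(
    list(tokens = tokens,
         token_to_id = setNames(seq_along(tokens) - 1L, tokens),
         class_of = setNames(class_of, tokens)),
    class = "ori_vocabulary")
}

#' Vocabulary size
#' @param vocab An `ori_vocabulary`.
#' @return Integer number of tokens.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Ids of the special tokens
#'
#' @param vocab An `ori_vocabulary`.
#' @return Named integer vector with elements `pad`, `bos`, `eos`, `sep`,
#'   `unk_species` (0-based ids).
#' @export
special_ids <- function(vocab) {
  setNames(vocab$token_to_id[SPECIAL_TOKENS],
           c("pad", "bos", "eos", "sep", "unk_species"))
}

#' Ids of a token class
#' @param vocab An `ori_vocabulary`.
#' @param class One of `"SPECIAL"`, `"SPECIES"`, `"AMINO_ACID"`, `"NUCLEOTIDE"`.
#' @return Unnamed integer vector of 0-based ids.
#' @export
class_ids <- function(vocab, class) {
  class <- match.arg(class, TOKEN_CLASSES)
  unname(vocab$token_to_id[vocab$class_of == class])
}

#' @export
print.ori_vocabulary <- function(x, ...) {
  tab <- table(factor(x$class_of, levels = TOKEN_CLASSES))
  cat(sprintf("ori_vocabulary: %d tokens (%s)\n", length(x$tokens),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write / read a vocabulary as plain text
#'
#' One token per line in id order; the token class is recorded after a tab.
#'
#' @param vocab An `ori_vocabulary`.
#' @param path File path.
#' @return `write_vocabulary`: `path`, invisibly. `read_vocabulary`: an
#'   `ori_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(paste(vocab$tokens, vocab$class_of, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "")
  new_vocabulary(tab[[1L]], tab[[2L]])
}
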