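#' Construct a replicon record
#'
#' A replicon record is one training/evaluation unit: a bacterial host
#' species label (or unknown), zero or more Rep initiator protein amino-acid
#' sequences, and the oriV nucleotide sequence. Nucleotides are lowercase
#' `a/c/g/t`; amino acids are the 20 uppercase one-letter codes, so the two
#' alphabets never collide.
#'
#' @param record_id Unique identifier string.
#' @param host_species Species label, or `NA` for unknown/unannotated hosts.
#' @param rep_proteins Character vector of amino-acid sequences (may be
#'   empty), ordered as they appear on the replicon.
#' @param oriv Non-empty lowercase nucleotide string over `acgt`.
#' @param group_label Optional group label (e.g. incompatibility group) used
#'   for subset training; `NA` if unknown.
#' @return An object of class `replicon_record`.
#' @examples
#' replicon_record("r1", "Escherichia_coli", c("MKV"), "acgtacgt")
#' @export
replicon_record <- function(record_id, host_species = NA_character_,
                            rep_proteins = character(), oriv,
                            group_label = NA_character_) {
  rec <- structure(
    list(record_id = as.character(record_id),
         host_species = as.character(host_species),
         rep_proteins = as.character(rep_proteins),
         oriv = as.character(oriv),
         group_label = as.character(group_label)),
    class = "replicon_record")
  validate_replicon_record(rec)
  rec
}

#' Validate a replicon record
#'
#' Checks the alphabet invariants: oriV non-empty over lowercase `acgt`,
#' Rep proteins over the 20 uppercase amino-acid letters. The offending
#' record and character offset are named in the error.
#'
#' @param rec A `replicon_record`.
#' @return `rec`, invisibly, if valid.
#' @export
validate_replicon_record <- function(rec) {
  stopifnot(inherits(rec, "replicon_record"))
  if (length(rec$oriv) != 1L || is.na(rec$oriv) || nchar(rec$oriv) == 0L)
    stop("record '", rec$record_id, "': oriv must be a non-empty string")
  .check_alphabet(rec$oriv, NUC_ALPHABET, rec$record_id, "oriv")
  for (k in seq_along(rec$rep_proteins)) {
    if (nchar(rec$rep_proteins[k]) == 0L)
      stop("record '", rec$record_id, "': rep protein ", k, " is empty")
    .check_alphabet(rec$rep_proteins[k], AA_ALPHABET, rec$record_id,
                    paste0("rep_protein[", k, "]"))
  }
  invisible(rec)
}

.check_alphabet <- function(s, alphabet, record_id, what) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop("record '", record_id, "': invalid character '", chars[bad[1L]],
         "' in ", what, " at offset ", bad[1L] - 1L, " (0-based)")
  }
  invisible(TRUE)
}

#' @export
print.replicon_record <- function(x, ...) {
  sp <- if (is.na(x$host_species)) "<unknown>" else x$host_species
  cat(sprintf("replicon_record '%s': host=%s, %d Rep protein(s), oriV %d nt\n",
              x$record_id, sp, length(x$rep_proteins), nchar(x$oriv)))
  invisible(x)
}

#' @export
format.replicon_record <- function(x, ...) {
  paste0("replicon_record(", x$record_id, ")")
}

is_unknown_species <- function(rec) {
  is.na(rec$host_species) || identical(rec$host_species, "")
}
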