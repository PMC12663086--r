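#' Read and write replicon corpora (FASTA + manifest)
#'
#' A corpus on disk is three files: an oriV FASTA (lowercase nucleotides),
#' a Rep FASTA (uppercase amino acids; may be absent or empty when no
#' record has a Rep), and a tab-separated manifest with columns
#' `record_id`, `host_species` (empty or `NA` for unknown), `rep_ids`
#' (comma-separated Rep FASTA ids in order, empty for none), `oriv_id`,
#' and optional `group_label`.
#'
#' @param manifest Path to the manifest TSV.
#' @param oriv_fasta Path to the oriV FASTA.
#' @param rep_fasta Path to the Rep FASTA, or `NULL`.
#' @return `read_replicons`: list of [replicon_record()].
#' @export
read_replicons <- function(manifest, oriv_fasta, rep_fasta = NULL) {
  man <- read.delim(manifest, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "")
  need <- c("record_id", "host_species", "rep_ids", "oriv_id")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  orivs <- .read_fasta(oriv_fasta)
  reps <- if (!is.null(rep_fasta) && file.exists(rep_fasta))
    .read_fasta(rep_fasta) else character(0)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    host <- row$host_species
    if (is.na(host) || host %in% c("", "NA", "UNKNOWN")) host <- NA_character_
    rep_ids <- if (is.na(row$rep_ids) || row$rep_ids == "") character(0)
      else strsplit(row$rep_ids, ",", fixed = TRUE)[[1L]]
    miss <- setdiff(c(rep_ids, row$oriv_id), names(c(reps, orivs)))
    if (length(miss)) stop("manifest references missing sequence id: ", miss[1L])
    replicon_record(
      record_id = row$record_id,
      host_species = host,
      rep_proteins = toupper(unname(reps[rep_ids])),
      oriv = tolower(unname(orivs[[row$oriv_id]])),
      group_label = if ("group_label" %in% names(row) &&
                        !is.na(row$group_label) && nzchar(row$group_label))
        row$group_label else NA_character_)
  })
}

#' @rdname read_replicons
#' @param records List of [replicon_record()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_replicons`: named list of the written paths, invisibly.
#' @export
write_replicons <- function(records, dir, prefix = "corpus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  oriv_path <- file.path(dir, paste0(prefix, "_oriv.fasta"))
  rep_path <- file.path(dir, paste0(prefix, "_rep.fasta"))
  orivs <- character(0); reps <- character(0)
  rows <- lapply(records, function(r) {
    oid <- paste0(r$record_id, "_oriv")
    orivs[[oid]] <<- r$oriv
    rep_ids <- character(0)
    for (k in seq_along(r$rep_proteins)) {
      rid <- paste0(r$record_id, "_rep", k)
      reps[[rid]] <<- r$rep_proteins[k]
      rep_ids <- c(rep_ids, rid)
    }
    data.frame(record_id = r$record_id,
               host_species = ifelse(is.na(r$host_species), "", r$host_species),
               rep_ids = paste(rep_ids, collapse = ","),
               oriv_id = oid,
               group_label = ifelse(is.na(r$group_label), "", r$group_label),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), man_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  .write_fasta(orivs, oriv_path)
  .write_fasta(reps, rep_path)
  invisible(list(manifest = man_path, oriv_fasta = oriv_path,
                 rep_fasta = rep_path))
}

.read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

.write_fasta <- function(seqs, path) {
  if (!length(seqs)) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a split assignment as TSV
#' @param split A `split_assignment` data.frame from [cluster_and_split()].
#' @param path File path.
#' @export
write_split <- function(split, path) {
  write.table(split, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  out <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = c("character", "integer", "character"))
  class(out) <- c("split_assignment", "data.frame")
  out
}
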