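# Pooled competition assay quantification: filtered read counting per
# origin variant, frequencies with pseudocount, log2 relative fitness,
# plus the small accounting helpers around the assay.

SAM_FLAG_UNMAPPED <- 0x4L
SAM_FLAG_SECONDARY <- 0x100L
SAM_FLAG_SUPPLEMENTARY <- 0x800L

#' Count reads per variant from filtered alignments
#'
#' A read contributes to its reference's count iff its mapping quality is
#' at least `min_mapq` (default 20) and it is a primary, mapped alignment
#' (secondary 0x100, supplementary 0x800 and unmapped 0x4 flags are all
#' excluded).
#'
#' @param alignments Data frame with columns `variant_ref` (reference
#'   name), `mapq`, `flag` (SAM flag integer), and optionally `sample_id`,
#'   `timepoint`, `replicate`, `condition` carried through to the output.
#' @param min_mapq Mapping-quality threshold (inclusive).
#' @return A `variant_count_table` data frame: one row per
#'   (variant, sample) with the filtered `count`.
#' @export
count_filtered_alignments <- function(alignments, min_mapq = 20L) {
  al <- as.data.frame(alignments)
  need <- c("variant_ref", "mapq", "flag")
  if (!all(need %in% names(al)))
    stop("alignments must have columns: ", paste(need, collapse = ", "))
  if (any(al$mapq < 0)) stop("negative MAPQ value")
  if (!"sample_id" %in% names(al)) al$sample_id <- "sample1"
  bad <- bitwAnd(as.integer(al$flag),
                 SAM_FLAG_UNMAPPED + SAM_FLAG_SECONDARY +
                   SAM_FLAG_SUPPLEMENTARY) != 0L
  keep <- al$mapq >= min_mapq & !bad
  kept <- al[keep, , drop = FALSE]
  tab <- aggregate(list(count = rep(1L, nrow(kept))),
                   by = list(variant_id = kept$variant_ref,
                             sample_id = kept$sample_id),
                   FUN = sum)
  # zero-count rows for variants seen in the input but filtered out
  all_pairs <- unique(al[, c("variant_ref", "sample_id")])
  names(all_pairs) <- c("variant_id", "sample_id")
  out <- merge(all_pairs, tab, all.x = TRUE)
  out$count[is.na(out$count)] <- 0L
  meta <- intersect(c("timepoint", "replicate", "condition"), names(al))
  if (length(meta)) {
    key <- unique(al[, c("sample_id", meta), drop = FALSE])
    out <- merge(out, key, by = "sample_id")
  }
  out <- out[order(out$sample_id, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_count_table", "data.frame")
  out
}

#' Read alignments from a SAM file for variant counting
#'
#' Thin ingestion path over Rsamtools (converted to BAM in a temporary
#' directory): extracts reference name, MAPQ and flag for every record so
#' the result can be fed to [count_filtered_alignments()]. Running the
#' aligner itself is out of scope.
#'
#' @param sam_path Path to a SAM file (with header).
#' @param sample_id Sample identifier attached to all reads.
#' @return Data frame with columns `variant_ref`, `mapq`, `flag`,
#'   `sample_id`.
#' @export
read_sam_alignments <- function(sam_path, sample_id = "sample1") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam_alignments requires the Rsamtools package")
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("rname", "mapq", "flag"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(variant_ref = as.character(x$rname),
             mapq = ifelse(is.na(x$mapq), 0L, x$mapq),
             flag = x$flag,
             sample_id = sample_id,
             stringsAsFactors = FALSE)
}

#' Variant frequencies with pseudocount
#'
#' Per sample, `f(v) = (count_v + pseudocount) / sum_v'(count_v' +
#' pseudocount)`; the pseudocount (default 1e-6) keeps every frequency
#' strictly positive so downstream log-ratios stay finite. Frequencies
#' sum to 1 within each sample.
#'
#' @param table A `variant_count_table` (or data frame with `variant_id`,
#'   `sample_id`, `count`).
#' @param pseudocount Added to every count before normalization.
#' @return The table with an additional `frequency` column.
#' @export
variant_frequencies <- function(table, pseudocount = 1e-6) {
  tab <- as.data.frame(table)
  need <- c("variant_id", "sample_id", "count")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$count < 0)) stop("negative count")
  if (anyDuplicated(tab[, c("variant_id", "sample_id")]))
    stop("duplicate (variant, sample) pair")
  adj <- tab$count + pseudocount
  tot <- ave(adj, tab$sample_id, FUN = sum)
  tab$frequency <- adj / tot
  class(tab) <- c("variant_count_table", "data.frame")
  tab
}

#' Log2 relative fitness of a variant
#'
#' `W = log2(f_tx / f_t0)`: the log2 ratio of a variant's frequency at a
#' later timepoint to its starting frequency in the matched pool. Zero
#' means neutral; -1 means the relative frequency halved.
#'
#' @param f_tx,f_t0 Strictly positive frequencies (the pseudocount
#'   guarantees this upstream).
#' @return Numeric W (vectorized).
#' @export
relative_fitness <- function(f_tx, f_t0) {
  if (any(f_tx <= 0) || any(f_t0 <= 0))
    stop("relative_fitness: frequencies must be > 0 ",
         "(was the pseudocount applied?)")
  log2(f_tx / f_t0)
}

#' Fitness table across timepoints
#'
#' Computes W for every variant and post-T0 sample against the matched
#' lineage's T0 frequency, where a lineage is a (replicate, condition)
#' pair and T0 is the row with the minimum timepoint.
#'
#' @param freq_table Output of [variant_frequencies()] including
#'   `timepoint`, `replicate`, `condition` columns.
#' @return Data frame with per-(variant, sample) `frequency` and `W`.
#' @export
fitness_table <- function(freq_table) {
  tab <- as.data.frame(freq_table)
  need <- c("variant_id", "sample_id", "timepoint", "replicate",
            "condition", "frequency")
  if (!all(need %in% names(tab)))
    stop("freq_table must have columns: ", paste(need, collapse = ", "))
  t0 <- min(tab$timepoint)
  base <- tab[tab$timepoint == t0,
              c("variant_id", "replicate", "condition", "frequency")]
  names(base)[names(base) == "frequency"] <- "f_t0"
  out <- merge(tab, base, by = c("variant_id", "replicate", "condition"))
  out$W <- relative_fitness(out$frequency, out$f_t0)
  out <- out[order(out$condition, out$replicate, out$timepoint,
                   out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generations of growth per serial passage
#'
#' A 1:`dilution_factor` dilution regrown to saturation corresponds to
#' `log2(dilution_factor)` doublings; the standard 1:100 passage is about
#' 6.6 generations.
#'
#' @param dilution_factor Fold-dilution per passage (>= 1).
#' @return Generations per passage.
#' @examples
#' generations_per_passage(100)  # 6.64
#' @export
generations_per_passage <- function(dilution_factor) {
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  log2(dilution_factor)
}

#' Plasmid-retention frequency from selective plating
#'
#' Fraction of colony-forming units that retain the plasmid: selected
#' (antibiotic-resistant) count over total count. Ratios slightly above 1
#' happen with plating noise; they are returned as-is with a warning flag
#' rather than clamped.
#'
#' @param n_selected,n_total Colony counts; `n_total` must be positive.
#' @return Numeric fraction with attribute `flagged` set when the ratio
#'   exceeds 1.
#' @export
stability_frequency <- function(n_selected, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_selected < 0) stop("n_selected must be non-negative")
  ratio <- n_selected / n_total
  if (ratio > 1)
    warning("stability frequency ", format(ratio),
            " exceeds 1 (plating noise?)")
  structure(ratio, flagged = ratio > 1)
}

#' Read / write variant count tables as TSV
#'
#' Columns: variant_id, sample_id, timepoint, replicate, condition, count.
#'
#' @param path File path.
#' @return `read_count_table`: a `variant_count_table` data frame.
#' @export
read_count_table <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, quote = "")
  need <- c("variant_id", "sample_id", "count")
  if (!all(need %in% names(tab)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  class(tab) <- c("variant_count_table", "data.frame")
  tab
}

#' @rdname read_count_table
#' @param table A `variant_count_table`.
#' @export
write_count_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
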