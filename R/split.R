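#' Cluster oriV sequences by identity and split clusters into partitions
#'
#' Greedy representative-based clustering in decreasing length order (the
#' CD-HIT contract without the external binary): each sequence joins the
#' first existing cluster whose representative (founder) shares at least
#' `identity_threshold` global-alignment identity (matches / alignment
#' length), otherwise it founds a new cluster. Whole clusters are then
#' assigned to TRAIN/VALID by shuffling the cluster ids under `seed` and
#' sending `round(valid_fraction * n_clusters)` of them to VALID, so no
#' cluster ever straddles the partitions.
#'
#' @param orivs Named character vector (or named list), id -> nucleotide
#'   sequence; at least two sequences.
#' @param identity_threshold Identity fraction in (0, 1]; default 0.90.
#' @param valid_fraction Fraction of clusters assigned to VALID; default 0.25.
#' @param seed Integer seed for the cluster shuffle.
#' @return A data.frame (class `split_assignment`) with columns
#'   `record_id`, `cluster` (integer), `partition` (`"TRAIN"`/`"VALID"`).
#' @export
cluster_and_split <- function(orivs, identity_threshold = 0.90,
                              valid_fraction = 0.25, seed = 1L) {
  seqs <- unlist(orivs)
  if (length(seqs) < 2L) stop("cluster_and_split: need at least 2 sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("cluster_and_split: sequences must be named")
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (valid_fraction < 0 || valid_fraction >= 1)
    stop("valid_fraction must be in [0, 1)")

  ord <- order(-nchar(seqs), names(seqs))  # length-sorted, ties by id
  reps <- character(0)      # representative sequences (cluster founders)
  assign <- integer(length(seqs))
  names(assign) <- names(seqs)[ord]
  for (i in seq_along(ord)) {
    s <- seqs[[ord[i]]]
    hit <- 0L
    for (ci in seq_along(reps)) {
      if (global_align(s, reps[ci])$identity_pct >= identity_threshold) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      hit <- length(reps)
    }
    assign[i] <- hit
  }

  n_clusters <- length(reps)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  shuffled <- sample.int(n_clusters)
  n_valid <- round(valid_fraction * n_clusters)
  valid_clusters <- shuffled[seq_len(n_valid)]
  out <- data.frame(
    record_id = names(assign),
    cluster = unname(assign),
    partition = ifelse(assign %in% valid_clusters, "VALID", "TRAIN"),
    stringsAsFactors = FALSE)
  out <- out[match(names(seqs), out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Remove near-duplicates of training sequences from a test set
#'
#' A test sequence is dropped iff some training sequence aligns to it with
#' identity above `identity_cut` over a region covering more than
#' `coverage_cut` of the test sequence. The check is a local-style
#' containment test built on the global aligner: terminal gap runs of the
#' global alignment are trimmed, identity is computed over the trimmed
#' core, and coverage is the fraction of test bases inside the core.
#' The operation is idempotent.
#'
#' @param test Named character vector of test sequences.
#' @param train Named or unnamed character vector of training sequences.
#' @param identity_cut Identity fraction above which a hit is a duplicate
#'   (strict inequality); default 0.95.
#' @param coverage_cut Test-coverage fraction (strict); default 0.95.
#' @return Character vector of retained test ids.
#' @export
filter_near_duplicates <- function(test, train, identity_cut = 0.95,
                                   coverage_cut = 0.95) {
  test <- unlist(test); train <- unlist(train)
  if (!length(test) || !length(train))
    stop("filter_near_duplicates: both sets must be non-empty")
  if (is.null(names(test)) || any(!nzchar(names(test))))
    stop("filter_near_duplicates: test sequences must be named")
  keep <- vapply(names(test), function(id) {
    q <- test[[id]]
    for (tr in train) {
      m <- .containment_stats(q, tr)
      if (m$identity > identity_cut && m$coverage > coverage_cut)
        return(FALSE)
    }
    TRUE
  }, logical(1))
  names(test)[keep]
}

# Identity/coverage of `query` within `ref` after trimming terminal gap
# runs from the global alignment. Coverage = aligned query bases in the
# trimmed core / query length.
.containment_stats <- function(query, ref) {
  aln <- global_align(query, ref)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  is_gap <- ca == "-" | cb == "-"
  core <- which(!is_gap)
  if (!length(core)) return(list(identity = 0, coverage = 0))
  lo <- min(core); hi <- max(core)
  idx <- lo:hi
  n_match <- sum(ca[idx] != "-" & ca[idx] == cb[idx])
  list(identity = n_match / length(idx),
       coverage = sum(ca[idx] != "-") / nchar(query))
}

# Seeded RNG scoping: run under a local seed, then restore the caller's
# RNG state so library functions do not perturb user-level reproducibility.
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
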