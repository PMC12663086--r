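#' Teacher-forced next-nucleotide accuracy on oriV regions
#'
#' For every oriV position of every record, the model predicts the next
#' token by argmax of [next_token_distribution()] conditioned on the true
#' preceding tokens (species and Rep context included); ties break by
#' token id. Accuracy is pooled over all oriV positions of all records
#' (the `<eos>` prediction is excluded), with a percentile bootstrap
#' confidence interval obtained by resampling sequences.
#'
#' @param model An `ori_model`.
#' @param records Non-empty list of [replicon_record()].
#' @param vocab The model's `ori_vocabulary`.
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return An `accuracy_report`: list with `n_sequences`, `n_positions`,
#'   `accuracy`, `ci_low`, `ci_high`, `n_resamples`, `seed`, and
#'   `per_sequence` (data.frame record_id / n_correct / n_positions).
#' @export
next_nucleotide_accuracy <- function(model, records, vocab,
                                     n_resamples = 1000L, level = 0.95,
                                     seed = 1L) {
  if (!length(records)) stop("next_nucleotide_accuracy: empty record list")
  per <- lapply(records, function(rec) {
    ids <- as.integer(encode_replicon(rec, vocab,
                                      context_len = model$config$context_len))
    pos <- oriv_token_positions(ids, vocab)
    if (!length(pos)) stop("record '", rec$record_id, "': no oriV positions")
    fw <- .fwd_batch(model$params, model$config, list(ids),
                     keep_cache = FALSE, dropout = 0,
                     logits_rows = pos - 1L)  # contexts ending just before
    pred <- max.col(fw$extra_logits, ties.method = "first") - 1L
    data.frame(record_id = rec$record_id,
               n_correct = sum(pred == ids[pos]),
               n_positions = length(pos))
  })
  per <- do.call(rbind, per)
  acc <- sum(per$n_correct) / sum(per$n_positions)
  ci <- bootstrap_ci(per[, c("n_correct", "n_positions")],
                     n_resamples = n_resamples, level = level, seed = seed)
  structure(list(n_sequences = nrow(per),
                 n_positions = sum(per$n_positions),
                 accuracy = acc, ci_low = ci[[1L]], ci_high = ci[[2L]],
                 n_resamples = as.integer(n_resamples), seed = as.integer(seed),
                 per_sequence = per),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "accuracy_report: %.1f%% (95%% CI %.1f-%.1f) over %d positions in %d sequences\n",
    100 * x$accuracy, 100 * x$ci_low, 100 * x$ci_high, x$n_positions,
    x$n_sequences))
  invisible(x)
}

#' Percentile bootstrap interval for pooled accuracy
#'
#' Sequences (not positions) are resampled with replacement — respecting
#' within-sequence correlation — and the pooled accuracy
#' `sum(n_correct) / sum(n_positions)` is recomputed per resample; the
#' interval is the percentile interval of the resampled statistics.
#'
#' @param per_sequence_scores Data frame (or 2-column matrix) with columns
#'   `n_correct`, `n_positions`; one row per sequence.
#' @param n_resamples Number of bootstrap resamples.
#' @param level Confidence level in (0, 1).
#' @param seed Seed.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(per_sequence_scores, n_resamples = 1000L,
                         level = 0.95, seed = 1L) {
  ps <- as.data.frame(per_sequence_scores)
  if (!all(c("n_correct", "n_positions") %in% names(ps)))
    stop("need columns n_correct and n_positions")
  if (!nrow(ps)) stop("bootstrap_ci: need at least one sequence")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n <- nrow(ps)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                nrow = n_resamples)
  corr <- matrix(ps$n_correct[idx], nrow = n_resamples)
  tot <- matrix(ps$n_positions[idx], nrow = n_resamples)
  stats <- rowSums(corr) / rowSums(tot)
  alpha <- (1 - level) / 2
  unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
}
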