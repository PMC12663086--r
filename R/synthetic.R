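#' Specification of a synthetic replicon corpus
#'
#' The generator emulates the family structure of natural plasmid
#' replicons: each family derives from one oriV template of the reference
#' median length (357 nt) carrying planted, verifiable functional
#' elements — a tandem iteron array (unit 17-22 nt, 3-5 copies), one
#' DnaA-box-like 9-mer, and an AT-rich block — plus a family-characteristic
#' Rep protein and host species label. Records are template copies with
#' i.i.d. random substitutions; substitutions inside planted elements are
#' applied at `mutation_rate * protected_factor`, emulating the purifying
#' selection that conserves functional elements in real origins (without
#' it, the corpus would carry no signal about which positions matter).
#'
#' @param n_families Number of replicon families.
#' @param n_per_family Records per family.
#' @param template_length oriV template length (default 357).
#' @param mutation_rate Per-position substitution rate outside planted
#'   elements, in \[0, 0.2\].
#' @param protected_factor Multiplier on the rate inside planted elements.
#' @param iteron_unit_range,iteron_copies_range Iteron repeat-unit length
#'   and tandem copy-number ranges (drawn once per family).
#' @param dnaa_length Length of the DnaA-box-like element.
#' @param at_block_length,at_fraction AT-rich block length and its exact
#'   AT fraction.
#' @param rep_fractions Probabilities of a record carrying 0, 1 or 2 Rep
#'   proteins. Default: always exactly one (Rep and oriV co-evolve within
#'   a family, and a fixed per-family Rep length keeps layouts aligned).
#' @param rep_length_range Rep protein length range (amino acids), drawn
#'   once per family.
#' @param seed Integer seed; corpora are byte-reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_families = 2L, n_per_family = 50L,
                           template_length = 357L, mutation_rate = 0.02,
                           protected_factor = 0.1,
                           iteron_unit_range = c(17L, 22L),
                           iteron_copies_range = c(3L, 5L),
                           dnaa_length = 9L,
                           at_block_length = 60L, at_fraction = 0.85,
                           rep_fractions = c(0, 1, 0),
                           rep_length_range = c(40L, 80L),
                           seed = 1L) {
  if (mutation_rate < 0 || mutation_rate > 0.2)
    stop("mutation_rate must be in [0, 0.2]")
  if (template_length < 1L || n_families < 1L || n_per_family < 1L)
    stop("all sizes must be positive")
  if (length(rep_fractions) != 3L || abs(sum(rep_fractions) - 1) > 1e-9)
    stop("rep_fractions must be 3 probabilities summing to 1")
  structure(list(n_families = as.integer(n_families),
                 n_per_family = as.integer(n_per_family),
                 template_length = as.integer(template_length),
                 mutation_rate = mutation_rate,
                 protected_factor = protected_factor,
                 iteron_unit_range = as.integer(iteron_unit_range),
                 iteron_copies_range = as.integer(iteron_copies_range),
                 dnaa_length = as.integer(dnaa_length),
                 at_block_length = as.integer(at_block_length),
                 at_fraction = at_fraction,
                 rep_fractions = rep_fractions,
                 rep_length_range = as.integer(rep_length_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a family-structured synthetic replicon corpus
#'
#' Builds family templates with planted elements, derives records by
#' seeded random substitution, and returns the records together with the
#' ground-truth coordinates of every planted element (0-based half-open)
#' and sharp PWMs (0.9 consensus probability per position) matching the
#' planted iteron unit and DnaA box of each family. The PWM hit threshold
#' is set to 90% of the maximal attainable score, so a hit call means a
#' near-exact (zero-mismatch) copy of the planted element.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (list of [replicon_record()]), `truth`
#'   (data.frame: record_id, family, element, start, end), `pwms`
#'   (list of [pwm()]), and `families` (per-family templates and labels).
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .save_rng(spec$seed)
  on.exit(.restore_rng(old))

  rand_nt <- function(n) paste(sample(NUC_ALPHABET, n, TRUE), collapse = "")
  rand_aa <- function(n) paste(sample(AA_ALPHABET, n, TRUE), collapse = "")
  rdraw <- function(rng) if (rng[1L] == rng[2L]) rng[1L] else
    sample(rng[1L]:rng[2L], 1L)

  families <- lapply(seq_len(spec$n_families), function(f) {
    unit_len <- rdraw(spec$iteron_unit_range)
    copies <- rdraw(spec$iteron_copies_range)
    unit <- rand_nt(unit_len)
    dnaa <- rand_nt(spec$dnaa_length)
    planted_len <- spec$at_block_length + unit_len * copies + spec$dnaa_length
    slack <- spec$template_length - planted_len
    if (slack < 4L)
      stop("planted elements (", planted_len,
           " nt) do not fit in the template length ", spec$template_length)
    # random spacer lengths around the three elements (order: AT, iteron, dnaA)
    cuts <- sort(sample.int(slack + 1L, 3L, replace = TRUE) - 1L)
    gaps <- c(cuts[1L], cuts[2L] - cuts[1L], cuts[3L] - cuts[2L],
              slack - cuts[3L])
    at_block <- .exact_at_block(spec$at_block_length, spec$at_fraction)
    segs <- c(rand_nt(gaps[1L]), at_block, rand_nt(gaps[2L]),
              strrep(unit, copies), rand_nt(gaps[3L]), dnaa,
              rand_nt(gaps[4L]))
    template <- paste(segs, collapse = "")
    at_start <- gaps[1L]
    it_start <- at_start + spec$at_block_length + gaps[2L]
    dn_start <- it_start + unit_len * copies + gaps[3L]
    elements <- rbind(
      data.frame(element = "at_block", start = at_start,
                 end = at_start + spec$at_block_length),
      data.frame(element = paste0("iteron_", seq_len(copies)),
                 start = it_start + (seq_len(copies) - 1L) * unit_len,
                 end = it_start + seq_len(copies) * unit_len),
      data.frame(element = "dnaa", start = dn_start,
                 end = dn_start + spec$dnaa_length))
    rep_len <- rdraw(spec$rep_length_range)
    list(family = f, template = template, elements = elements,
         iteron_unit = unit, dnaa = dnaa,
         species = sprintf("Synthobacter_familiae_%02d", f),
         rep_templates = c(rand_aa(rep_len), rand_aa(rdraw(spec$rep_length_range))))
  })

  protected <- lapply(families, function(fam) {
    prot <- logical(spec$template_length)
    for (i in seq_len(nrow(fam$elements))) {
      prot[(fam$elements$start[i] + 1L):fam$elements$end[i]] <- TRUE
    }
    prot
  })

  records <- list()
  truth <- list()
  for (f in seq_len(spec$n_families)) {
    fam <- families[[f]]
    rate <- rep(spec$mutation_rate, spec$template_length)
    rate[protected[[f]]] <- spec$mutation_rate * spec$protected_factor
    for (i in seq_len(spec$n_per_family)) {
      rid <- sprintf("fam%d_rec%03d", f, i)
      n_reps <- sample(0:2, 1L, prob = spec$rep_fractions)
      reps <- if (n_reps > 0L) {
        vapply(fam$rep_templates[seq_len(n_reps)], .mutate_aa,
               character(1), rate = spec$mutation_rate)
      } else character(0)
      records[[length(records) + 1L]] <- replicon_record(
        rid, fam$species, reps,
        .mutate_nt(fam$template, rate),
        group_label = paste0("fam", f))
      truth[[length(truth) + 1L]] <- cbind(
        data.frame(record_id = rid, family = f), fam$elements)
    }
  }

  pwms <- unlist(lapply(families, function(fam) {
    list(.sharp_pwm(sprintf("fam%d_iteron", fam$family), fam$iteron_unit),
         .sharp_pwm(sprintf("fam%d_dnaa", fam$family), fam$dnaa))
  }), recursive = FALSE)

  list(records = records, truth = do.call(rbind, truth), pwms = pwms,
       families = families, spec = spec)
}

.exact_at_block <- function(len, at_fraction) {
  n_at <- round(at_fraction * len)
  chars <- c(sample(c("a", "t"), n_at, TRUE),
             sample(c("c", "g"), len - n_at, TRUE))
  paste(sample(chars), collapse = "")
}

.mutate_nt <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(NUC_ALPHABET, chars[i]), 1L)
  paste(chars, collapse = "")
}

.mutate_aa <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  paste(chars, collapse = "")
}

# Sharp PWM for a planted element: consensus probability 0.9, the rest
# split evenly; threshold at 90% of the maximal score (near-exact calls).
.sharp_pwm <- function(name, consensus, consensus_prob = 0.9) {
  chars <- strsplit(tolower(consensus), "", fixed = TRUE)[[1L]]
  probs <- matrix((1 - consensus_prob) / 3, nrow = length(chars), ncol = 4)
  probs[cbind(seq_along(chars), match(chars, NUC_ALPHABET))] <- consensus_prob
  p <- pwm(name, probs)
  p$score_threshold <- 0.9 * pwm_max_score(p)
  p
}

#' The twelve-motif restriction-site avoidance fixture
#'
#' The common type II restriction-modification recognition motifs used for
#' the constraint-guided generation experiments, already filtered to
#' length >= 3 and at most five degenerate positions. Also shipped as
#' `inst/extdata/restriction_motifs.txt`.
#'
#' @return Character vector of twelve IUPAC patterns.
#' @export
make_motif_fixture <- function() {
  c("GATC", "CCWGG", "GGTCTC", "GAAABCC", "GRGCYC", "CCGCGG",
    "CTGCAG", "CCNGG", "GGYRCC", "CRARCAG", "GAATTC", "CCTNAGG")
}

#' Write a synthetic corpus to disk
#'
#' Emits the standard manifest + FASTA files consumed by
#' [read_replicons()], the planted-element truth table as TSV, and the
#' matching PWM file.
#'
#' @param corpus Output of [make_corpus()].
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  paths <- write_replicons(corpus$records, dir)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(corpus$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pwm_path <- file.path(dir, "planted_pwms.txt")
  write_pwms(corpus$pwms, pwm_path)
  invisible(c(paths, list(truth = truth_path, pwms = pwm_path)))
}
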