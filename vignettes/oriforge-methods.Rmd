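---
title: "Modeling and designing plasmid replication origins with oriforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and designing plasmid replication origins with oriforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plasmid replication is controlled by a compact cis-acting locus, the
origin of vegetative replication (oriV), often acting together with a
plasmid-encoded replication initiator (Rep) protein and shaped by the
bacterial host. Natural oriVs carry recognizable but incompletely
understood functional elements — AT-rich regions that ease strand
opening, tandem direct repeats (iterons) bound by Rep, DnaA boxes bound
by the host initiator — embedded in otherwise variable sequence.
`oriforge` treats the replicon as a categorical sequence-modeling
problem: a record is the host species label, the ordered Rep protein
sequence(s), and the oriV nucleotide sequence, and a decoder-only
autoregressive transformer is trained to predict each token from its
predecessors. A trained model supports host- and Rep-conditioned
sampling of new origins, constraint-guided decoding that provably avoids
forbidden restriction-site motifs, and a set of in-silico plausibility
metrics and controls around the generations.

## Tokenization and data model

Records are tokenized as: `<bos>`, one species token (or
`<unk_species>`), the Rep amino acids with `<sep>` between multiple
Reps, individual lowercase nucleotides for the oriV, `<eos>`. Lowercase
nucleotides versus uppercase amino-acid letters keep the two alphabets
disjoint, so one flat vocabulary carries both. Token ids are assigned
deterministically (specials, then sorted species, then the 20 amino
acids, then `a c g t`), making vocabularies order-independent and
reproducible. Records longer than the context window (default 1500
tokens) are rejected rather than truncated: silent truncation would
corrupt oriV boundaries. A `<bos>` token is introduced explicitly; with
it, unconditioned generation can let the model choose the species
itself. All internal coordinates are 0-based, half-open.

Train/validation splitting is leakage-aware: sequences are clustered
greedily in decreasing length order, joining the first cluster whose
founder shares at least 90% global-alignment identity
(matches / alignment length, gaps in the denominator), and whole
clusters are assigned to partitions. The assignment shuffles clusters
under the seed and moves `round(0.25 * n)` of them to validation —
a deterministic allocation whose fraction is exact, rather than an
independent coin flip per cluster. Near-duplicate filtering of a test
set removes sequences for which some training sequence exceeds 95%
identity over more than 95% of the test sequence (computed from the
global alignment after trimming terminal gap runs, a local-style
containment check).

## The sequence model

The model is a pre-norm decoder-only transformer with learned absolute
positional embeddings, causal multi-head attention, GELU feed-forward
blocks, and an output head tied to the token embedding matrix. With the
reference configuration (12 layers, 12 heads, embedding dimension 768,
feed-forward 3072, vocabulary 145, context 1500) the closed-form
trainable-parameter count is 86,319,360 — approximately 86M — and the
package asserts at model construction that the instantiated tensors
realize exactly the closed form. Tying the head is what lands the
reference configuration at that count; an untied head would add another
111k x 768 block.

Training minimizes next-token cross-entropy over all positions (species
and Rep included — evaluation later restricts to oriV positions) with
AdamW (decoupled weight decay 0.1 on weight matrices, dropout 0.1 by
default, constant learning rate, global gradient-norm clipping at 1.0),
shuffled minibatches of whole sequences, and early stopping on
validation loss with a patience counter; the best-validation checkpoint
is returned. The implementation is plain R: the heavy operations are
BLAS matrix products, minibatches concatenate sequences row-wise (never
padded) with attention computed per sequence, and the hand-derived
backward pass is verified against central finite differences in the test
suite. Generation uses an incremental decoder with per-layer key/value
caches that is asserted equal to the full forward pass.

The learning rate and batch size of the original training run are not
published; the defaults here (3e-3, 16) are tuned for the desk-scale
configurations used in the tests and make no fidelity claim.

Per-sequence embeddings are the arithmetic mean over positions of the
final-layer hidden states by default ("token embeddings" is ambiguous
between input embeddings and contextual states; the contextual choice
separates structure better and the alternative is available as
`type = "input"`). The choice travels with the result as an attribute.

## Generation and constraints

Sampling supports nucleus (top-p = 0.95) and top-k (k = 4) truncation at
temperature 1.0 by default, with temperature 0 defined as the argmax
limit. Continuations are restricted by a small grammar mask to tokens
that keep the sequence a valid layout prefix, so every generation
decodes to a replicon record.

Constraint-guided generation expands IUPAC motifs to their concrete
variants, closes the set under reverse complement (so forward-strand
scanning covers both strands), and runs deterministic beam search in
which a candidate extension whose rolling suffix window (spanning the
prompt/generation boundary) completes a forbidden motif is pruned before
scoring. Beams are ranked by total log-likelihood with ties broken by
token id. Because the stop token is always admissible inside the oriV
region, a fully-pruned set of nucleotide extensions still terminates via
`<eos>`; truly unsatisfiable constraint sets therefore collapse to short
motif-free outputs rather than failures, and the explicit infeasibility
error remains as a defensive boundary. Whether the original procedure
applied the constraint during beam scoring or as post-filtering is not
stated; pruning-during-search is implemented here. Prompts whose seed
already contains a forbidden motif must first be repaired with
`infill_repair()`, which substitutes single bases inside the leftmost
occurrence, choosing the substitution with the highest full-sequence
autoregressive likelihood, until the sequence is motif-free.

## Evaluation

Next-nucleotide accuracy is teacher-forced: at every oriV position the
model's argmax prediction (ties by token id) is compared with the true
nucleotide, conditioning on the true preceding tokens including the
species and Rep context; the `<eos>` prediction is excluded as a
token-scheme artifact. Confidence intervals are percentile bootstrap
(default 1000 resamples) resampling sequences, not positions, which
respects within-sequence correlation; BCa refinements were judged
unnecessary for the pooled statistic.

## In-silico validation metrics

AT content is the fraction of A/T positions. Folding energy is computed
on 100-bp windows at step 1; the engine is pluggable, and the built-in
stand-in is a Nussinov maximum Watson-Crick base-pairing count (minimum
hairpin loop 3) negated — always non-positive, zero for homopolymers,
and with no claim of thermodynamic equivalence to a real folding engine;
any function from window to energy (e.g. a wrapper around an external
thermodynamic folder) can be supplied. Motif scanning sums per-position
log-likelihood ratios (uniform 0.25 background by default) at every
offset on both strands and calls hits above the PWM's threshold (1.0 by
default, the conventional log-likelihood cutoff; the p-value machinery
of heavier scanners is deliberately not reproduced — the stated filter
is the score cutoff). The random baseline is i.i.d. uniform ACGT of
length 357, the median oriV length in the reference training corpus.

## Similarity and matched mutants

Similarity to the closest wild type is the percent identity of a true
global (end-gap-penalized) affine-gap alignment, Gotoh three-state DP
with a gap run of length L costing `gap_open + L * gap_extend`
(10.0 / 0.5), match +5 / mismatch -4 (the EMBOSS nucleotide defaults;
the substitution scores are a recorded choice since only the tool and
gap penalties are published). Traceback ties resolve diagonal > up >
left, making alignments deterministic. Candidate wild types are ranked
by shared 11-mer count before the single global alignment — a BLAST-like
prefilter with no external binary; when no k-mer is shared the package
falls back to aligning against every reference. Matched random mutants
apply the aligned edit spectrum (substitutions, insertions, deletions)
at seeded-random positions of the wild type, deletions first, then
insertions, then substitutions; because edits interact, re-aligned
controls can drift a few identity points from their targets, which is
expected and tested only at that tolerance.

## Fitness statistics

Reads count toward a variant when MAPQ >= 20 and the alignment is
primary and mapped (secondary 0x100, supplementary 0x800, unmapped 0x4
are excluded). Frequencies add a 1e-6 pseudocount to every count before
per-sample normalization — applied to the counts, literally — so
log-ratios stay finite; relative fitness is W = log2(f_tx / f_t0)
against the matched lineage's (replicate x condition) T0. A 1:100
serial passage corresponds to log2(100) = 6.64 generations. Stability
ratios above 1 (plating noise) are flagged, not clamped.

## The synthetic corpus: what it emulates and what it does not

Every stage is testable without downloads through a family-structured
synthetic corpus. Each family has one 357-nt oriV template carrying a
planted tandem iteron array (unit 17-22 nt, 3-5 copies), one 9-nt
DnaA-box-like element, and an AT-rich block (fraction 0.85 over 60 nt),
plus a family-specific host label and one Rep protein whose length
(40-80 aa) is drawn once per family so records of a family share a
layout. Records are template copies with i.i.d. substitutions at rate
0.02 — except inside planted elements, where the rate is divided by 10.
This purifying-selection emulation is deliberate: conserved functional
elements amid variable backbone are precisely the signal that lets a
trained model preserve motifs while varying elsewhere, and without it
motif-preservation experiments would be vacuous because model noise and
random control noise would hit motifs at identical rates. Emitted PWMs
are sharp (0.9 consensus probability) with thresholds at 90% of the
maximal score, so a hit call means a near-exact element copy and a
single substitution inside an element removes its call — making
retention and destruction measurable at desk scale.

What the corpus does not emulate: real oriV length variation, indel
processes, GC-skew and host-composition signals, Rep-oriV biochemical
compatibility, and incompatibility-group semantics beyond the family
label. Passing tests therefore demonstrate that the pipeline's machinery
behaves as specified on family-structured data with conserved elements,
not that the desk-scale model would reproduce results on natural
plasmid corpora.

## Desk-scale experiment sizes and numerical choices

The test suite trains three models chosen to fit comfortably in CPU
minutes: a 2-layer, 2-head, d = 64 model on the default 2-family corpus
(100 records, 34 epochs), the same architecture on 80 GATC-saturated
60-nt records, and a single-sequence memorization run. On the 2-family
corpus the held-out teacher-forced oriV accuracy reaches ~98%, far above
the 25% uniform baseline and the 0.60 bar asserted in the tests. The
motif-preservation experiment conditions generation on a family's
species and Rep (top-k sampling, k = 4, temperature 1.0 — the setting
used for prompted validation generations; nucleus sampling at p = 0.95
on a converged desk-scale model collapses to argmax and yields
near-exact template copies, which would make the matched-mutant control
vacuous). Generated origins land in the low-to-mid 90s of percent
identity to their closest wild type, retain the planted iteron in the
vast majority of draws against an essentially-zero random baseline,
while matched random mutants lose at least one iteron copy in the
majority (roughly two thirds) of draws.

Other numerical choices: layer norm epsilon 1e-5; initialization is
N(0, 0.02) with output-projection scaling 0.02 / sqrt(2 L) and N(0,
0.01) positional embeddings; validation improvement below 1e-6 counts as
no improvement for patience; softmax computations subtract row maxima;
the nucleus prefix uses a 1e-12 slack on the cumulative-mass comparison
so exact boundary masses are included deterministically; PAD positions,
if ever present, are masked from the loss. Seeds flow explicitly into
every stochastic operation (corpus generation, splitting, training
shuffles and dropout, sampling, mutants), and seeded operations restore
the caller's RNG state on exit.

## Known limitations

The transformer is CPU-oriented and practical only at desk scale; no
mixed precision or accelerator support is provided, and the reference
86M configuration is instantiable but not trainable here in reasonable
time. The stand-in folding engine is a pairing count, not a free-energy
model. The greedy clusterer matches the identity-threshold contract of
the standard tool but not its bit-exact cluster boundaries. BLAST-style
E-values, FIMO p-values, and external-database parsing are out of scope
by design; the corresponding contracts (top-candidate selection, score
cutoff) are preserved.
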