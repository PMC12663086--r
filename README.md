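# oriforge

Autoregressive language modeling and constraint-guided design of plasmid
origins of replication (oriVs), for researchers building replicating
vectors or studying plasmid replication loci.

A plasmid replicon is modeled as one token sequence — the bacterial host
species as a single token, the Rep initiator protein(s) as amino-acid
tokens, and the oriV as lowercase nucleotide tokens:

```
<bos> species [rep aa ... <sep> rep aa ...] a c g t ... <eos>
```

A decoder-only transformer (learned positional embeddings, causal
multi-head attention, output head tied to the token embedding; the
reference configuration of 12 layers x 12 heads at d = 768 over a
1500-token context counts ~86M parameters) is trained on such sequences
with AdamW and early stopping, and then used to:

- **generate** new origins, optionally conditioned on a host species, a
  Rep protein, and/or a seed prefix, via nucleus (top-p = 0.95) or
  top-k (k = 4) sampling at temperature 1.0;
- **generate under constraints**: IUPAC restriction-site motifs are
  expanded, closed under reverse complement, and excluded during beam
  search, so outputs provably contain no forbidden site on either
  strand; prompt seeds are repaired with model-guided infill
  substitutions;
- **evaluate** teacher-forced next-nucleotide accuracy on oriV regions
  with sequence-level bootstrap confidence intervals;
- **validate in silico**: AT content, sliding-window folding energy
  (pluggable engine; Nussinov stand-in built in), PWM motif scanning
  (log-likelihood ratios, both strands) against a length-357 uniform
  random baseline;
- **compare to wild types**: affine-gap global alignment (Needleman-
  Wunsch/Gotoh, gap open 10.0 / extend 0.5, match +5 / mismatch -4)
  behind a k-mer prefilter, with matched random-mutant controls that
  replay the aligned edit spectrum at random positions;
- **score pooled fitness assays**: MAPQ >= 20 primary-alignment
  counting, 1e-6 pseudocount frequencies, W = log2(f_tx / f_t0), and
  passage accounting (1:100 dilution = 6.64 generations).

Identity-aware dataset splitting (greedy 90%-identity clustering, whole
clusters assigned 75/25), a near-duplicate test filter (>95% identity
over >95% coverage), and a synthetic corpus generator with planted,
verifiable iterons / DnaA boxes / AT-rich blocks make the whole pipeline
testable end to end without external data. See the methods vignette
(`vignettes/oriforge-methods.Rmd`) for the model, assumptions, and
design choices.

## Worked example

```r
library(oriforge)

# a tiny corpus with planted, verifiable elements
corpus <- make_corpus(synthetic_spec(n_per_family = 5, seed = 7))
vocab  <- build_vocabulary(corpus$records)
vocab
#> ori_vocabulary: 31 tokens (SPECIAL=5, SPECIES=2, AMINO_ACID=20, NUCLEOTIDE=4)

# the reference architecture instantiates ~86M trainable parameters
count_parameters(model_config(vocab_size = 145))
#> [1] 86319360

# similarity of "acgt" to "aagt": one substitution under EMBOSS-style scoring
global_align("acgt", "aagt")
#> alignment_result: score 11.0, identity 75.0%, 1 sub / 0 ins / 0 del over 4 columns

# restriction motifs expand to reverse-complement-closed concrete sets
expand_motifs("CCWGG")
#> [1] "CCAGG" "CCTGG"

# the planted iteron is found at its ground-truth coordinates
scan_pwm(corpus$families[[1]]$template, corpus$pwms[[1]])[1:2, ]
#>         motif start end strand    score
#> 1 fam1_iteron   191 209      + 23.05681
#> 2 fam1_iteron   209 227      + 23.05681

# pooled-fitness accounting
generations_per_passage(100)
#> [1] 6.643856
relative_fitness(f_tx = 0.05, f_t0 = 0.1)
#> [1] -1
```

`scan_pwm` scores are summed log-likelihood ratios against a uniform
background; 23.06 is the maximal score of the 18-nt planted iteron PWM,
so the template carries five exact tandem copies starting at position
191 (0-based). Training, generation and evaluation follow the same API
(`train_model()`, `generate()`, `generate_constrained()`,
`next_nucleotide_accuracy()`); see the vignette and the test suite for
complete desk-scale runs.

A command-line wrapper for the whole pipeline ships in
`inst/cli/oriforge` (subcommands `make-fixtures`, `build-vocab`,
`split`, `train`, `generate`, `generate-constrained`, `evaluate`,
`validate-insilico`, `similarity`, `mutate`, `strip-sites`, `fitness`,
`expand-motifs`); every run writes a provenance record beside its
outputs.

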