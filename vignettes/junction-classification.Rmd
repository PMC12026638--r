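---
title: "Classifying circRNA back-splice junctions from flanking sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying circRNA back-splice junctions from flanking sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circbsj)
```

## The problem

Circular RNAs (circRNAs) arise from back-splicing: a downstream 5' splice
donor is joined to an upstream 3' acceptor, producing a covalently closed
transcript. The two back-splice sites and the sequence immediately around
them carry the signal that distinguishes a circRNA from a linear
transcript, so a practical way to recognise circRNAs from annotation alone
is to classify a short window of genomic sequence around those two sites.
`circbsj` implements that pipeline end to end: it takes a genome FASTA and
two BED files (circRNA positives, long noncoding RNA negatives), builds a
fixed-length *junction feature sequence* per record, embeds each
nucleotide as a vector, and trains a small neural network to separate the
two classes.

## Feature-sequence construction

For an interval `(chrom, start, end, strand)` the two back-splice sites
are taken to be the interval's start and end coordinates (BED semantics:
0-based half-open). Around each site we take `flank_len` nucleotides on
each side — 50 by default — giving two 100-nt windows, which are
concatenated into one 200-nt feature sequence:

* plus strand: `[start-50, start+50)` then `[end-50, end+50)`;
* minus strand: the reverse complement of that concatenation, so the
  acceptor-side window always comes first in transcript orientation.

Choices worth making explicit, because annotation formats leave them
open:

* **Sites = span endpoints.** Multi-exon transcripts have internal
  structure we deliberately ignore; only the BED span's endpoints define
  the junction. If your annotation stores exon blocks, flatten them to
  the back-splice span first.
* **Window order is acceptor-first** (configurable in spirit: the model
  is symmetric to a consistent swap, since convolution and pooling are
  position-blind after training).
* **Records without a strand column default to `+`.**
* **Windows that run off the chromosome are skipped and counted**, never
  silently truncated; an `oob = "pad"` option N-pads instead if you must
  keep every record.
* **Duplicates are removed on the extracted feature sequence**, not the
  record name, mirroring how merged public catalogues are deduplicated.

`split_dataset()` assigns train/validation/test at 80/10/10 by default,
stratified by class, with `floor` rules per class and the remainder going
to train: 1,000 records become exactly 800/100/100.

## Embedding contract

Every embedder maps a length-`L` sequence to an `(L+2) x D` matrix; the
two extra rows are begin/end sentinel rows mirroring the boundary tokens
that nucleic-acid foundation models prepend and append, which is why a
200-nt feature embeds to 202 rows. Three embedders share the contract:

* `one_hot` (`D = 4`): `A,C,G,T` to unit vectors, `N` and sentinels to
  zero rows. The sparse low-dimensional baseline.
* `mock` (`D = 2560` by default): a deterministic pseudo-random embedding
  keyed by (position, token, seed). It carries no biology; it exists so
  every shape, caching and training path can be exercised offline at the
  foundation-model dimensionality. One substituted base changes exactly
  one row.
* `external`: an adapter slot for a real pretrained model. The user
  supplies `fun(sequence) -> matrix`; the package validates the
  `(L+2) x D` shape and finiteness and enforces the 1280-nt input cap
  typical of such models. Everything else works when no adapter is
  installed.

Embeddings are precomputed in memory once per run; at the problem sizes
this package targets (hundreds to a few thousand records) a disk cache
would add complexity without measurable benefit.

## The classifier

The network is deliberately small and entirely defined by
`model_config()`:

1. **Convolution module** — `length(conv_channels)` blocks of 1-D
   convolution (odd `kernel_size`, default 3, symmetric zero padding so
   the position count is preserved), a normalization layer, and
   LeakyReLU (`leaky_slope`, default 0.01, multiplies negative inputs).
   Default widths are `(256, 128, 64)`.
2. **Self-attention** — queries, keys and values are independent linear
   maps of the convolution features,
   `X_att = softmax(Q K' / sqrt(D_k)) V`, optionally multi-head
   (`attention_heads`, default 4) by slicing the width. Each row of the
   attention matrix is a probability distribution over positions. The
   scaled dot-product form is sometimes printed with `K'Q` inside the
   softmax; that orientation is dimensionally inconsistent with row-wise
   normalization over keys, so the standard `QK'` form is implemented.
   `use_attention = FALSE` gives the ablated variant.
3. **Adaptive max pooling** — output size 1 per channel: the feature
   vector is the columnwise maximum over positions. Max pooling rather
   than mean pooling because the discriminative signal is expected to be
   local (at or near the splice sites), and a maximum detects presence
   regardless of position.
4. **Fully connected classifier** — `z = W y + b` to two logits
   (`linear_layers = 1` by default; deeper stacks interleave LeakyReLU),
   then a numerically stable softmax (max-subtraction) and cross-entropy
   loss with the log clamped at `1e-12`.

### Normalization

The type of the normalization layer inside the convolution blocks is a
genuinely open design point. This package normalizes each position's
channel vector (layer normalization with learnable per-channel scale and
shift), not batch statistics: a per-example rule keeps every forward pass
independent of batch composition, which is what makes bit-for-bit
reproducibility and exact batched-vs-single prediction agreement
attainable, and needs no running statistics at inference.
`norm = "none"` disables it.

### Training

`train_config()` defaults: Adam, learning rate **0.005**, batch size 64,
early stopping on validation loss with patience 5, everything seeded.
Optimizer, batch size and epoch count are conventions, not reproductions
of any published recipe. The backward pass is derived by hand for every
block (convolution via patch-matrix multiplication, layer norm,
attention, max-pool argmax routing, the linear stack) and is verified in
the test suite against central finite differences at relative tolerance
`1e-4`. Divergence (non-finite loss or activations) aborts with a
diagnostic rather than propagating NaN. An optional
`class_weights = "balanced"` applies inverse-frequency loss weights for
imbalanced catalogues; the default leaves examples unweighted and the
decision rule is argmax (threshold 0.5).

## What the synthetic generator emulates

`synthetic_spec()` describes a toy genome (4 chromosomes x 70 kb by
default) with i.i.d. bases, plus 250 positive and 250 negative intervals
placed in non-overlapping slots so flank windows never collide. The one
property of real data it reproduces is the one the classifier relies on:
*discriminative sequence concentrated at the back-splice sites*. For a
`motif_rate` fraction of positives (default 1.0), two splice-site-like
motifs are written into the genome — `TTTAG` ending exactly at the
acceptor site and `AGGTAAGT` just inside the donor-side window — on
either strand, respecting transcript orientation. Negatives are
placement-matched random intervals, so interval length and base
composition cannot act as confounds. The motif content and offsets are
arbitrary fixtures echoing the canonical GT/AG dinucleotide context;
nothing else about real circRNA biology (secondary structure, Alu
repeats, reverse-complement pairing, non-uniform genome composition,
overlapping genes) is modelled. Passing tests on this generator
demonstrate that the pipeline can recover a planted junction-proximal
signal — not that it attains any particular accuracy on real catalogues,
which additionally require a real genome and a real embedder.

`generate_separable_embeddings()` sidesteps sequence entirely: two
standard-normal clusters whose means differ by `margin` along one
coordinate of one row. It unit-tests the classifier in isolation with a
known linear solution.

## Numerical and degenerate-input choices

* Softmax always subtracts the row maximum; cross-entropy clamps
  probabilities at `1e-12`.
* Layer normalization uses variance epsilon `1e-5`.
* Max-pooling ties break to the first (lowest-index) position,
  deterministically; permutation invariance of the pooled *values* still
  holds.
* Metrics with zero denominators (e.g. precision of a never-positive
  predictor) are reported as 0 with a warning instead of NaN; MCC's
  denominator rule is the same.
* Parameter initialization is seeded uniform fan-in
  (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`); all randomness in a run
  derives from the configured seeds, so a (seed, data, config) triple
  fixes metrics bit-for-bit on CPU.
* FASTA headers are truncated at the first whitespace; sequences are
  uppercased, `U` becomes `T`, and any other non-ACGT character becomes
  `N`. `N` embeds to a zero row under one-hot.

## Problem sizes used in the shipped checks

The package's own verification runs at desk scale, chosen so the full
suite trains several models from scratch in a few minutes: the
learnability checks use the generator defaults (500 records, so 400
train / 100 test under an 80/20 split with no validation set), the
one-hot embedder, a narrowed convolution stack `(32, 24, 16)`, and 25
epochs at the default learning rate. For the planted-signal recovery
surrogate the convolution-only ablation (`use_attention = FALSE`,
`norm = "none"`) is used: at these sample sizes and epoch budgets the
attention layer — whose initial near-uniform weights average features
across all positions before pooling — needs substantially more epochs to
converge reliably, and the surrogate's purpose is to verify signal
recovery, not to benchmark the full architecture. The full
attention-bearing forward/backward path is exercised and
gradient-checked separately.

## A worked example

```{r, eval = FALSE}
spec <- synthetic_spec(seed = 1)
bundle <- simulate_bundle(spec, "toy_run")
genome <- read_fasta("toy_run/genome.fasta")
ds <- build_dataset(read_bed("toy_run/positives.bed", "circRNA"),
                    read_bed("toy_run/negatives.bed", "lncRNA"),
                    genome)
ds <- split_dataset(ds, c(0.8, 0, 0.2), seed = 1)
emb <- embedder("one_hot")
tr <- ds[ds$split == "train", ]
te <- ds[ds$split == "test", ]
fit <- train(embed_all(emb, tr$sequence), tr$label,
             model_config(conv_channels = c(32, 24, 16), norm = "none",
                          use_attention = FALSE),
             train_config(epochs = 25, batch_size = 32, seed = 1,
                          early_stop_patience = 25))
evaluate(fit$params, fit$config, embed_all(emb, te$sequence), te$label)
```

The same workflow is available from a shell through the CLI wrapper
(`inst/cli/circbsj.R`): `simulate`, `extract`, `train`, `predict`,
`evaluate`.

## Known limitations

* No real-data ingestion beyond FASTA/BED: no GTF/GFF transcript models,
  no BSJ detection from reads, no database download clients.
* The external-embedder path is an adapter contract, not a bundled
  model; nothing here reproduces published foundation-model accuracies.
* Binary classification only (circRNA vs lncRNA negatives).
* Training is single-threaded CPU R; it is sized for hundreds to a few
  thousand examples, not genome-scale catalogues.
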