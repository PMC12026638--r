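# circbsj

Back-splice junction feature extraction and circRNA classification in R.

## The problem

Circular RNAs (circRNAs) form when a downstream 5' splice donor is joined
back to an upstream 3' acceptor, leaving a distinctive back-splice
junction (BSJ). The sequence immediately flanking the two back-splice
sites carries enough signal to distinguish circRNAs from linear
transcripts such as long noncoding RNAs (lncRNAs). `circbsj` is for
computational biologists who have a genome FASTA plus BED annotations of
candidate circRNAs and lncRNA negatives and want a tested, fully
reproducible classifier over the junction-flanking sequence.

The pipeline:

1. **Feature extraction** — for each interval, take 50 nt on each side of
   the start (acceptor-side) and end (donor-side) coordinates and merge
   the two 100-nt windows into one 200-nt feature sequence, acceptor side
   first in transcript orientation (minus-strand records are
   reverse-complemented).
2. **Embedding** — map each feature sequence to an `(L+2) x D` matrix
   (two boundary sentinel rows, so 202 rows for 200 nt): `one_hot`
   (`D = 4`), a deterministic `mock` at foundation-model width
   (`D = 2560`), or an `external` adapter wrapping a pretrained
   nucleic-acid language model.
3. **Classification** — a stack of 1-D convolutions (LeakyReLU, optional
   per-position normalization), a scaled dot-product self-attention layer
   `X_att = softmax(QK'/sqrt(D_k))V`, adaptive max pooling
   `Y_j = max_i X_att[i, j]`, and a fully connected layer `z = W Y + b`
   with softmax and cross-entropy loss `L = -log p_true`, trained with
   seeded minibatch Adam (default learning rate 0.005, 80/10/10
   stratified splits).

Standard metrics (accuracy, precision, recall/sensitivity, F1, Matthews
correlation coefficient) come from the confusion table of the argmax
decision rule.

A synthetic-data module generates toy genomes with splice-site-like
motifs planted at the junctions of positive records, so the complete
pipeline can be exercised and validated offline.

## Worked example

```r
library(circbsj)

spec <- synthetic_spec(seed = 1)          # 250 circRNA-like + 250 lncRNA-like
bundle <- simulate_bundle(spec, "toy_run")

genome <- read_fasta("toy_run/genome.fasta")
ds <- build_dataset(read_bed("toy_run/positives.bed", "circRNA"),
                    read_bed("toy_run/negatives.bed", "lncRNA"),
                    genome)                       # 500 x 200-nt features
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

Output:

```
$confusion
$confusion$tp
[1] 50
$confusion$fp
[1] 0
$confusion$tn
[1] 50
$confusion$fn
[1] 0

$metrics
$metrics$accuracy
[1] 1
$metrics$precision
[1] 1
$metrics$recall
[1] 1
$metrics$f1
[1] 1
$metrics$mcc
[1] 1
```

All 100 held-out junctions are classified correctly: every planted
positive carries the acceptor (`TTTAG`) and donor (`AGGTAAGT`) motifs at
its junction windows, so a converged model should recover essentially all
of them, and the perfect confusion table says exactly that. On data with
`motif_rate = 0` (no signal) the same run sits at chance (accuracy 0.5).

The same workflow is scriptable from a shell:

```sh
Rscript inst/cli/circbsj.R simulate --out toy_run --seed 1
Rscript inst/cli/circbsj.R train --genome toy_run/genome.fasta \
    --pos toy_run/positives.bed --neg toy_run/negatives.bed \
    --out run1 --embedder one_hot --seed 1
Rscript inst/cli/circbsj.R predict --checkpoint run1/checkpoint.rds \
    --features features.tsv --out predictions.tsv
```

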