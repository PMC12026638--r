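Package: circbsj
Title: Back-Splice Junction Feature Extraction and circRNA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies circular RNAs (circRNAs) from genomic annotations by
    classifying back-splice junction feature sequences against long noncoding
    RNA (lncRNA) negatives. Extracts strand-aware 200-nt junction feature
    sequences (50 nt flanking each back-splice site) from a genome FASTA and
    labeled BED intervals, embeds them through interchangeable per-nucleotide
    embedders (one-hot, a deterministic mock, or an adapter to an external
    nucleic-acid foundation model honouring a fixed (L+2) x D shape contract),
    and classifies with a convolution / self-attention / adaptive-max-pooling /
    fully-connected network trained by cross-entropy. Includes a synthetic-data
    generator that plants splice-site motifs into toy genomes so the whole
    pipeline is testable offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
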