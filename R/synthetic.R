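#' Specification for synthetic benchmark data
#'
#' Describes a toy genome plus planted-motif interval sets that emulate the
#' one statistical handle the classification task relies on: discriminative
#' sequence signal concentrated at and around the two back-splice sites.
#' Positive (circRNA-like) records carry splice-site-like motifs written
#' into the genome inside both junction flank windows; negative
#' (lncRNA-like) records are placement-matched random intervals with no
#' planted signal, so length and base-composition confounds are controlled.
#'
#' The default motifs echo the canonical splice signals: `TTTAG`
#' (polypyrimidine run + AG) ends exactly at the acceptor-side site and
#' `AGGTAAGT` (GT-donor consensus) sits just inside the donor-side window.
#' Their content and offsets are arbitrary fixtures.
#'
#' @param n_chromosomes,chrom_length Toy genome shape (default 4 x 70 kb).
#' @param n_pos,n_neg Number of positive / negative records (default
#'   250 each).
#' @param motif_donor,motif_acceptor Motifs planted at the donor-side and
#'   acceptor-side windows of positives; each must be shorter than
#'   `flank_len`.
#' @param motif_rate Fraction of positives that carry the motifs
#'   (default 1.0). At 0 the classes are statistically indistinguishable.
#' @param label_noise Probability that a record's emitted BED label is
#'   flipped (default 0); the ground-truth manifest keeps the true label.
#' @param base_composition Named numeric vector of A/C/G/T frequencies
#'   (default uniform).
#' @param flank_len Flank width the downstream extraction will use
#'   (default 50); placement keeps all windows inside chromosomes.
#' @param interval_length Length range (min, max) of generated intervals.
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   spec.
#' @return A list of class `bsj_synthetic_spec`.
#' @export
synthetic_spec <- function(n_chromosomes = 4L, chrom_length = 70000L,
                           n_pos = 250L, n_neg = 250L,
                           motif_donor = "AGGTAAGT", motif_acceptor = "TTTAG",
                           motif_rate = 1.0, label_noise = 0,
                           base_composition = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                           flank_len = 50L, interval_length = c(200L, 400L),
                           seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chrom_length >= 1L, n_pos >= 1L, n_neg >= 1L,
            motif_rate >= 0, motif_rate <= 1, label_noise >= 0, label_noise <= 1,
            length(base_composition) == 4L, all(base_composition >= 0),
            abs(sum(base_composition) - 1) < 1e-8,
            nchar(motif_donor) < flank_len - 2L,
            nchar(motif_acceptor) <= flank_len,
            length(interval_length) == 2L,
            interval_length[1L] <= interval_length[2L],
            interval_length[1L] > 0L)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 motif_donor = motif_donor, motif_acceptor = motif_acceptor,
                 motif_rate = motif_rate, label_noise = label_noise,
                 base_composition = base_composition,
                 flank_len = as.integer(flank_len),
                 interval_length = as.integer(interval_length),
                 seed = as.integer(seed)),
            class = "bsj_synthetic_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Generate a toy genome
#'
#' I.i.d. bases drawn from the spec's base composition; deterministic per
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `bsj_genome` (named character vector `chr1`, `chr2`, ...).
#' @export
generate_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "bsj_synthetic_spec"))
  seqs <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_chromosomes), function(i) {
      paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE,
                   prob = spec$base_composition), collapse = "")
    }, "")
  })
  names(seqs) <- paste0("chr", seq_len(spec$n_chromosomes))
  structure(seqs, class = "bsj_genome")
}

# Feature-coordinate offsets at which motifs are planted in positives:
# the acceptor motif ends exactly at the acceptor site (feature offset
# flank - nchar(acceptor)); the donor motif starts 2 nt after the donor
# site (feature offset 3*flank + 2).
motif_offsets <- function(spec) {
  list(acceptor = spec$flank_len - nchar(spec$motif_acceptor),
       donor = 3L * spec$flank_len + 2L)
}

# Write `motif` into `genome` so that it appears at `feature_offset` of the
# transcript-oriented feature sequence of the given interval.
plant_motif <- function(genome, chrom, start, end, strand, flank, feature_offset,
                        motif) {
  m <- nchar(motif)
  stopifnot(feature_offset >= 0L, feature_offset + m <= 4L * flank)
  if (strand == "-") {
    # feature = revcomp(product): feature [o, o+m) maps to product
    # [4f-o-m, 4f-o) carrying the reverse complement of the motif
    feature_offset <- 4L * flank - feature_offset - m
    motif <- reverse_complement(motif)
  }
  # product offset -> genomic position
  if (feature_offset + m <= 2L * flank) {
    gpos <- start - flank + feature_offset        # acceptor-side window
  } else if (feature_offset >= 2L * flank) {
    gpos <- end - flank + (feature_offset - 2L * flank)
  } else {
    stop("motif placement crosses the window boundary")
  }
  s <- genome[[chrom]]
  substr(s, gpos + 1L, gpos + m) <- motif
  genome[[chrom]] <- s
  genome
}

#' Plant labeled records into a toy genome
#'
#' Places non-overlapping intervals (windows included) on the chromosomes,
#' writes the spec's motifs into the genome at fixed feature-sequence
#' offsets for a `motif_rate` fraction of the positives (on both strands,
#' respecting transcript orientation), applies label noise to the emitted
#' BED labels, and returns the modified genome together with the interval
#' tables and a ground-truth manifest.
#'
#' @param genome A `bsj_genome` from [generate_toy_genome()].
#' @param spec The same [synthetic_spec()] used for the genome.
#' @return List with `genome` (motifs written in), `positives` and
#'   `negatives` (interval data.frames carrying the emitted, possibly
#'   noise-flipped labels), and `manifest` (data.frame with true labels,
#'   motif presence, and planted offsets).
#' @export
plant_records <- function(genome, spec) {
  stopifnot(inherits(spec, "bsj_synthetic_spec"))
  n_total <- spec$n_pos + spec$n_neg
  flank <- spec$flank_len
  slot <- spec$interval_length[2L] + 2L * flank + 20L
  per_chrom <- (spec$chrom_length - 2L * flank) %/% slot
  if (per_chrom * spec$n_chromosomes < n_total) {
    stop("too many records (", n_total, ") for the available genome space (",
         per_chrom * spec$n_chromosomes, " slots)")
  }
  offs <- motif_offsets(spec)
  with_seed(spec$seed + 7L, {
    slots <- seq_len(n_total) - 1L
    chrom_id <- slots %% spec$n_chromosomes + 1L
    slot_id <- slots %/% spec$n_chromosomes
    is_pos <- c(rep(TRUE, spec$n_pos), rep(FALSE, spec$n_neg))
    len <- sample(seq(spec$interval_length[1L], spec$interval_length[2L]),
                  n_total, replace = TRUE)
    jitter_max <- pmax(slot - len - 2L * flank, 1L)
    jitter <- floor(stats::runif(n_total) * jitter_max)
    start <- flank + slot_id * slot + jitter
    end <- start + len
    strand <- sample(c("+", "-"), n_total, replace = TRUE)
    has_motif <- is_pos & (stats::runif(n_total) < spec$motif_rate)
    flipped <- stats::runif(n_total) < spec$label_noise
    for (i in which(has_motif)) {
      genome <- plant_motif(genome, paste0("chr", chrom_id[i]), start[i],
                            end[i], strand[i], flank, offs$acceptor,
                            spec$motif_acceptor)
      genome <- plant_motif(genome, paste0("chr", chrom_id[i]), start[i],
                            end[i], strand[i], flank, offs$donor,
                            spec$motif_donor)
    }
    true_label <- ifelse(is_pos, "circRNA", "lncRNA")
    emit_label <- ifelse(xor(is_pos, flipped), "circRNA", "lncRNA")
    id <- sprintf("%s_%04d", ifelse(is_pos, "pos", "neg"),
                  c(seq_len(spec$n_pos), seq_len(spec$n_neg)))
    manifest <- data.frame(id = id, chrom = paste0("chr", chrom_id),
                           start = start, end = end, strand = strand,
                           true_label = true_label, emitted_label = emit_label,
                           motif_present = has_motif,
                           acceptor_offset = offs$acceptor,
                           donor_offset = offs$donor,
                           stringsAsFactors = FALSE)
    iv <- data.frame(chrom = manifest$chrom, start = start, end = end,
                     name = id, strand = strand, label = emit_label,
                     stringsAsFactors = FALSE)
    list(genome = genome,
         positives = iv[iv$label == "circRNA", , drop = FALSE],
         negatives = iv[iv$label == "lncRNA", , drop = FALSE],
         manifest = manifest)
  })
}

#' Generate and write a complete synthetic fixture bundle
#'
#' Convenience wrapper: toy genome, planted records, FASTA + two BED files
#' + ground-truth TSV manifest under `out_dir`.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory `genome`, `positives`,
#'   `negatives`, `manifest` and the written `paths`.
#' @export
simulate_bundle <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_toy_genome(spec)
  pr <- plant_records(g, spec)
  paths <- list(genome = file.path(out_dir, "genome.fasta"),
                positives = file.path(out_dir, "positives.bed"),
                negatives = file.path(out_dir, "negatives.bed"),
                manifest = file.path(out_dir, "manifest.tsv"))
  write_fasta(pr$genome, paths$genome)
  write_bed(pr$positives, paths$positives)
  write_bed(pr$negatives, paths$negatives)
  utils::write.table(pr$manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pr, list(paths = paths)))
}

#' Generate linearly separable embedding sets
#'
#' Unit-tests the classifier in isolation: two standard-normal clusters in
#' embedding space whose class means differ by `margin` along a single
#' coordinate of a fixed row, wrapped into `(n_positions+2) x dim`
#' matrices. At `margin = 0` the classes are identically distributed.
#'
#' @param n_per_class Examples per class.
#' @param dim Embedding dimension.
#' @param margin Separation between class means along the signal
#'   coordinate.
#' @param seed Integer seed.
#' @param n_positions Sequence length L of the wrapped matrices.
#' @param signal_row Row index carrying the class signal (default 3).
#' @return List with `embeddings` (length `2*n_per_class`), `y` (labels
#'   0/1), `signal_row`, `signal_col`.
#' @export
generate_separable_embeddings <- function(n_per_class, dim = 8L, margin = 10,
                                          seed = 1L, n_positions = 10L,
                                          signal_row = 3L) {
  stopifnot(margin >= 0, signal_row >= 1L, signal_row <= n_positions + 2L)
  with_seed(seed, {
    n <- 2L * n_per_class
    y <- rep(c(0L, 1L), each = n_per_class)
    embeddings <- lapply(seq_len(n), function(i) {
      m <- matrix(stats::rnorm((n_positions + 2L) * dim), n_positions + 2L, dim)
      m[signal_row, 1L] <- m[signal_row, 1L] + ifelse(y[i] == 1L, margin / 2,
                                                      -margin / 2)
      m
    })
    list(embeddings = embeddings, y = y, signal_row = signal_row,
         signal_col = 1L)
  })
}
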