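#' Read a genome FASTA file
#'
#' Parses a (multi-)FASTA file into a named character vector of chromosome
#' sequences. Headers are truncated at the first whitespace, sequences are
#' uppercased, `U` is mapped to `T`, and every character outside `{A,C,G,T}`
#' (IUPAC ambiguity codes, gaps, ...) is mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `bsj_genome`: one uppercase
#'   sequence over the alphabet `{A,C,G,T,N}` per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 toy", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- normalize_sequence(as.character(recs))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(nm[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- nm
  structure(seqs, class = "bsj_genome")
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences (a `bsj_genome`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Uppercase, RNA->DNA, anything non-ACGT -> N.
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

#' Read labeled intervals from a BED file
#'
#' Standard BED semantics: 0-based half-open coordinates, tab-separated,
#' at least three columns. Column 4 (if present) provides the record name,
#' otherwise names are auto-generated; column 6 (if present) provides the
#' strand, otherwise `+` is assumed. Every record carries the supplied
#' class label.
#'
#' @param path Path to a BED file (3-6 columns).
#' @param label Class label attached to every record, e.g. `"circRNA"`
#'   for positives or `"lncRNA"` for negatives.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, `label`. Empty files yield a zero-row data.frame.
#' @export
read_bed <- function(path, label) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  stopifnot(is.character(label), length(label) == 1L)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) stop("BED line with fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) stop("non-integer coordinates in BED file: ", path)
  if (any(start < 0L)) stop("negative start coordinate in BED file: ", path)
  bad <- start >= end
  if (any(bad)) {
    stop("start >= end for BED record(s) at line(s): ",
         paste(which(bad), collapse = ", "))
  }
  name <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else paste0(label, "_", i)
  }, "")
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L && nzchar(f[[6L]])) f[[6L]] else "+"
  }, "")
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, label = label, stringsAsFactors = FALSE)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), strand = character(), label = character(),
             stringsAsFactors = FALSE)
}

#' Write intervals to a BED file
#'
#' Emits 6-column BED (name in column 4, `0` score placeholder in column 5,
#' strand in column 6) so that [read_bed()] round-trips coordinates exactly.
#'
#' @param intervals Interval data.frame as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", intervals$chrom, intervals$start,
                   intervals$end, intervals$name, intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return The reverse complement of each sequence (`N` maps to `N`).
#' @examples
#' reverse_complement("ACGTN")  # "NACGT"
#' @export
reverse_complement <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("illegal character in sequence (alphabet is A,C,G,T,N)")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract the back-splice junction feature sequence for one interval
#'
#' Takes `flank_len` nucleotides on each side of the two back-splice sites
#' (the interval's start and end coordinates) and merges the two
#' `2*flank_len` windows into one feature sequence of length `4*flank_len`
#' (200 nt at the default flank of 50). On the plus strand the window
#' centred on the start (the splice-acceptor side of the back-splice
#' junction) comes first, followed by the window centred on the end (the
#' donor side). Minus-strand intervals yield the reverse complement of the
#' plus-strand product, which puts the acceptor-side window first in
#' transcript orientation.
#'
#' @param interval A one-row interval data.frame (see [read_bed()]).
#' @param genome A `bsj_genome` from [read_fasta()].
#' @param flank_len Nucleotides taken on each side of each site (default 50).
#' @param oob How to treat windows that run off the chromosome: `"error"`
#'   (default) fails, `"pad"` fills the missing positions with `N`.
#' @return A character scalar of length `4*flank_len` with attributes
#'   `name`, `label`, `flank_len`.
#' @export
extract_junction_flanks <- function(interval, genome, flank_len = 50L,
                                    oob = c("error", "pad")) {
  oob <- match.arg(oob)
  stopifnot(flank_len >= 1L)
  chrom <- interval$chrom
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chrom_seq <- genome[[chrom]]
  clen <- nchar(chrom_seq)
  w1 <- flank_window(chrom_seq, clen, interval$start, flank_len, oob)
  w2 <- flank_window(chrom_seq, clen, interval$end, flank_len, oob)
  feat <- paste0(w1, w2)
  if (identical(interval$strand, "-")) feat <- reverse_complement(feat)
  structure(feat, name = interval$name, label = interval$label,
            flank_len = as.integer(flank_len))
}

# One 2*flank window centred on a 0-based site coordinate.
flank_window <- function(chrom_seq, clen, site, flank_len, oob) {
  lo <- site - flank_len        # 0-based inclusive
  hi <- site + flank_len        # 0-based exclusive
  if (lo < 0L || hi > clen) {
    if (oob == "error") {
      stop("flank window [", lo, ", ", hi, ") out of chromosome bounds (length ",
           clen, ")")
    }
    core <- substr(chrom_seq, max(lo, 0L) + 1L, min(hi, clen))
    return(paste0(strrep("N", max(0L, -lo)), core, strrep("N", max(0L, hi - clen))))
  }
  substr(chrom_seq, lo + 1L, hi)
}

#' Build a labeled feature-sequence dataset
#'
#' Runs [extract_junction_flanks()] over positive (circRNA) and negative
#' (lncRNA) interval sets, drops records whose flank windows fall outside
#' their chromosome, and removes duplicate feature sequences keeping the
#' first occurrence. Positives are labeled `1`, negatives `0`.
#'
#' @param pos,neg Interval data.frames (see [read_bed()]).
#' @param genome A `bsj_genome`.
#' @param flank_len Flank width per side per site (default 50).
#' @return A data.frame with columns `id`, `sequence`, `label` and attributes
#'   `kept`, `skipped`, `deduplicated` counting what happened during
#'   extraction.
#' @export
build_dataset <- function(pos, neg, genome, flank_len = 50L) {
  extract_all <- function(iv, y) {
    n <- nrow(iv)
    seqs <- character(n)
    keep <- logical(n)
    for (i in seq_len(n)) {
      s <- tryCatch(extract_junction_flanks(iv[i, , drop = FALSE], genome,
                                            flank_len = flank_len),
                    error = function(e) NA_character_)
      if (!is.na(s)) {
        seqs[i] <- s
        keep[i] <- TRUE
      }
    }
    data.frame(id = iv$name[keep], sequence = seqs[keep],
               label = rep(y, sum(keep)), stringsAsFactors = FALSE)
  }
  dpos <- extract_all(pos, 1L)
  dneg <- extract_all(neg, 0L)
  skipped <- (nrow(pos) - nrow(dpos)) + (nrow(neg) - nrow(dneg))
  if (skipped > 0L) {
    message(skipped, " interval(s) skipped: flank window out of chromosome bounds")
  }
  ds <- rbind(dpos, dneg)
  dup <- duplicated(ds$sequence)
  if (any(dup)) {
    message(sum(dup), " duplicate feature sequence(s) removed")
    ds <- ds[!dup, , drop = FALSE]
  }
  if (!any(ds$label == 1L)) stop("no positive examples survived extraction")
  if (!any(ds$label == 0L)) stop("no negative examples survived extraction")
  rownames(ds) <- NULL
  structure(ds, kept = nrow(ds), skipped = skipped, deduplicated = sum(dup))
}

#' Assign train/validation/test splits
#'
#' Stratified by label: within each class, `floor(n * ratio)` examples go to
#' validation and test and the remainder to train, so the 80/10/10 default
#' sends 800/100/100 of 1000 examples to the three partitions. Deterministic
#' given `seed`.
#'
#' @param ds Dataset from [build_dataset()].
#' @param ratios Numeric length-3 vector `(train, validation, test)` summing
#'   to 1. Default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed controlling the shuffle.
#' @return `ds` with an added `split` column over
#'   `{"train", "validation", "test"}`.
#' @export
split_dataset <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8, all(ratios >= 0))
  if (nrow(ds) == 0L) stop("empty dataset")
  split <- character(nrow(ds))
  n_parts <- sum(ratios > 0)
  for (y in unique(ds$label)) {
    idx <- which(ds$label == y)
    n <- length(idx)
    if (n < n_parts) {
      stop("class ", y, " has too few examples (", n, ") for a ", n_parts,
           "-way split")
    }
    n_val <- floor(n * ratios[2L])
    n_test <- floor(n * ratios[3L])
    idx <- idx[rand_perm(n, seed + y)]
    split[idx[seq_len(n_val)]] <- "validation"
    split[idx[seq_len(n_test) + n_val]] <- "test"
    split[idx[seq(n_val + n_test + 1L, n)]] <- "train"
  }
  ds$split <- split
  ds
}

# Seeded permutation that leaves the caller's RNG state untouched.
rand_perm <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  sample.int(n)
}

#' Write feature sequences as TSV
#'
#' Two/three-column tab-separated output (`id`, `sequence`, and `label` when
#' present) for extracted junction feature sequences.
#'
#' @param ds Dataset data.frame with at least `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(ds, path) {
  cols <- intersect(c("id", "sequence", "label", "split"), names(ds))
  utils::write.table(ds[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read feature sequences from TSV or FASTA
#'
#' @param path Path to either a TSV written by [write_features_tsv()] or a
#'   FASTA file of pre-extracted feature sequences.
#' @return A data.frame with `id`, `sequence` and, if available, `label`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) > 0L && startsWith(first, ">")) {
    g <- read_fasta(path)
    return(data.frame(id = names(g), sequence = as.character(unclass(g)),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = NA)
  stopifnot(all(c("id", "sequence") %in% names(df)))
  df$sequence <- normalize_sequence(df$sequence)
  df
}
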