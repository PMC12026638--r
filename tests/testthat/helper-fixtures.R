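# Shared fixtures built in code at test time.

# A deterministic random chromosome string of given length.
toy_chrom <- function(len, seed = 11) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

toy_genome <- function(lens = c(chr1 = 300L), seed = 11) {
  g <- vapply(seq_along(lens), function(i) toy_chrom(lens[[i]], seed + i), "")
  names(g) <- names(lens)
  structure(g, class = "bsj_genome")
}

interval_row <- function(chrom, start, end, strand = "+", name = "iv1",
                         label = "circRNA") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, label = label, stringsAsFactors = FALSE)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

# Strip attributes so sequence payloads compare as plain strings.
chr <- function(x) {
  attributes(x) <- NULL
  x
}

# A small model configuration that keeps unit tests fast.
tiny_config <- function(...) {
  model_config(conv_channels = c(8L, 6L), attention_heads = 2L, ...)
}
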