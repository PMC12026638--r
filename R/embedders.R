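#' Construct an embedder specification
#'
#' All embedders honour one shape contract: a length-`L` nucleotide string
#' becomes an `(L+2) x D` numeric matrix, the two extra rows being
#' begin/end sentinel rows emulating the boundary tokens of a nucleic-acid
#' foundation model (a 200-nt feature sequence therefore embeds to
#' 202 rows).
#'
#' * `one_hot` — `D = 4`; `A,C,G,T` map to unit vectors in that fixed order,
#'   `N` to the zero row, sentinels to zero rows. The low-dimensional
#'   ablation baseline.
#' * `mock` — `D = 2560` by default; a deterministic pseudo-random stand-in
#'   with the same shape as a foundation-model embedding. Each row is a pure
#'   hash of (position, token, seed), so identical inputs give bit-identical
#'   matrices and a single substituted base changes exactly one row.
#' * `external` — delegates to a user-supplied adapter function
#'   (`fun(sequence) -> matrix`), e.g. wrapping a pretrained language model;
#'   the returned matrix is validated against the shape contract. Input
#'   length is capped at `max_len` (default 1280, the typical context limit
#'   of such models).
#'
#' @param kind One of `"one_hot"`, `"mock"`, `"external"`.
#' @param dim Embedding dimension `D`. Fixed at 4 for `one_hot`; default
#'   2560 otherwise.
#' @param seed Integer seed (used by the mock embedder only).
#' @param fun Adapter function for `kind = "external"`.
#' @param max_len Maximum input length for the external adapter.
#' @return An object of class `bsj_embedder`.
#' @export
embedder <- function(kind = c("one_hot", "mock", "external"), dim = NULL,
                     seed = 0L, fun = NULL, max_len = 1280L) {
  kind <- match.arg(kind)
  if (kind == "one_hot") {
    if (!is.null(dim) && dim != 4L) stop("one_hot embedder has fixed dim 4")
    dim <- 4L
  } else if (is.null(dim)) {
    dim <- 2560L
  }
  stopifnot(dim >= 1L)
  id <- switch(kind,
               one_hot = "one_hot",
               mock = sprintf("mock_d%d_s%d", dim, as.integer(seed)),
               external = sprintf("external_d%d", dim))
  structure(list(kind = kind, dim = as.integer(dim), seed = as.integer(seed),
                 fun = fun, max_len = as.integer(max_len), id = id),
            class = "bsj_embedder")
}

#' @export
print.bsj_embedder <- function(x, ...) {
  cat("<bsj_embedder>", x$id, "(D =", x$dim, ")\n")
  invisible(x)
}

#' Embed a nucleotide sequence
#'
#' Dispatches on the embedder kind and validates the `(L+2) x D` shape
#' contract and finiteness of every entry before returning.
#'
#' @param emb A `bsj_embedder` from [embedder()].
#' @param seq A nucleotide string over `{A,C,G,T,N}`.
#' @return An `(nchar(seq)+2) x dim` numeric matrix with attributes
#'   `embedder_id` and `source_length`.
#' @export
embed_sequence <- function(emb, seq) {
  stopifnot(inherits(emb, "bsj_embedder"), is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) {
    stop("illegal character in sequence (alphabet is A,C,G,T,N)")
  }
  m <- switch(emb$kind,
              one_hot = one_hot_embed(seq),
              mock = mock_embed(seq, emb),
              external = external_embed(seq, emb))
  validate_embedding(m, nchar(seq), attr(m, "embedder_id") %||% emb$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_embedding <- function(m, L, id) {
  if (!is.matrix(m) || !is.numeric(m)) stop("embedding is not a numeric matrix")
  if (nrow(m) != L + 2L) {
    stop("embedding shape contract violated: expected ", L + 2L,
         " rows for a ", L, "-nt input, got ", nrow(m))
  }
  if (!all(is.finite(m))) stop("non-finite values in embedding")
  attr(m, "embedder_id") <- id
  attr(m, "source_length") <- L
  m
}

#' One-hot embedding
#'
#' `A,C,G,T` map to the four unit vectors in that order, `N` and both
#' sentinel rows to the zero vector, giving an `(L+2) x 4` matrix.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @return `(nchar(seq)+2) x 4` numeric matrix.
#' @export
one_hot_embed <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(bases)
  m <- matrix(0, nrow = L + 2L, ncol = 4L)
  code <- match(bases, c("A", "C", "G", "T"))   # N -> NA -> zero row
  hit <- which(!is.na(code))
  m[cbind(hit + 1L, code[hit])] <- 1
  attr(m, "embedder_id") <- "one_hot"
  m
}

#' Deterministic mock embedding
#'
#' A shape-faithful stand-in for a foundation-model embedding: row `i` is a
#' reproducible pseudo-random vector in `[-1, 1]^D` derived by hashing the
#' (position, token, seed) triple, where the tokens are the nucleotide at
#' each position plus begin/end boundary tokens for the sentinel rows.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @param emb A `bsj_embedder` with `kind = "mock"` (supplies `dim`, `seed`).
#' @return `(nchar(seq)+2) x dim` numeric matrix.
#' @export
mock_embed <- function(seq, emb) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  tokens <- c("<s>", bases, "</s>")
  codes <- match(tokens, c("A", "C", "G", "T", "N", "<s>", "</s>"))
  D <- emb$dim
  m <- matrix(0, nrow = length(tokens), ncol = D)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (i in seq_along(tokens)) {
    h <- (as.numeric(emb$seed) * 1009 + (i - 1) * 131 + codes[[i]]) %% 2147483647
    set.seed(as.integer(h))
    m[i, ] <- stats::runif(D, -1, 1)
  }
  attr(m, "embedder_id") <- emb$id
  m
}

#' External foundation-model embedding adapter
#'
#' Delegates embedding to a user-supplied function wrapping a pretrained
#' nucleic-acid language model. The toolkit itself never loads such a model;
#' it only enforces the `(L+2) x D` shape contract on whatever the adapter
#' returns, so every other embedder keeps working when no adapter is
#' installed.
#'
#' @param seq Nucleotide string.
#' @param emb A `bsj_embedder` with `kind = "external"` and a non-`NULL`
#'   `fun`.
#' @return The adapter's `(nchar(seq)+2) x dim` matrix, validated.
#' @export
external_embed <- function(seq, emb) {
  if (is.null(emb$fun)) {
    stop("external embedding adapter not installed: supply `fun` to embedder()")
  }
  if (nchar(seq) > emb$max_len) {
    stop("sequence length ", nchar(seq), " exceeds the adapter maximum of ",
         emb$max_len)
  }
  m <- emb$fun(seq)
  if (is.matrix(m) && ncol(m) != emb$dim) {
    stop("embedding shape contract violated: expected ", emb$dim,
         " columns, got ", ncol(m))
  }
  attr(m, "embedder_id") <- emb$id
  m
}

#' Embed every sequence of a dataset
#'
#' @param emb A `bsj_embedder`.
#' @param sequences Character vector of feature sequences.
#' @return A list of embedding matrices, one per sequence.
#' @export
embed_all <- function(emb, sequences) {
  lapply(sequences, function(s) embed_sequence(emb, s))
}
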