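#' Classifier configuration
#'
#' Configuration of the junction classifier head: a stack of 1-D
#' convolution blocks (convolution, per-position normalization over
#' channels, LeakyReLU), one multi-head self-attention layer, global
#' adaptive max pooling (output size 1 per channel), and a fully connected
#' classifier emitting two logits (circRNA vs. not).
#'
#' @param conv_channels Integer vector of output channels per convolution
#'   layer; its length is the number of convolution layers (default three
#'   layers, `c(256, 128, 64)`).
#' @param kernel_size Odd convolution kernel width (default 3); positions
#'   are preserved by symmetric zero padding.
#' @param leaky_slope Negative-side slope of LeakyReLU (default 0.01).
#' @param norm `"layer"` (normalize each position's channel vector, with
#'   learnable per-channel scale and shift) or `"none"`.
#' @param use_attention Include the self-attention layer (`FALSE` gives the
#'   attention-ablated variant).
#' @param attention_heads Number of attention heads (default 4); must
#'   divide the final convolution width.
#' @param linear_layers Number of linear layers in the classifier
#'   (default 1; hidden layers use LeakyReLU).
#' @param fc_hidden Width of hidden linear layers when `linear_layers > 1`.
#' @param dropout Dropout probability on the pooled vector during training
#'   (default 0).
#' @param num_classes Number of output classes (fixed binary task, 2).
#' @return A validated list of class `bsj_model_config`.
#' @export
model_config <- function(conv_channels = c(256L, 128L, 64L),
                         kernel_size = 3L,
                         leaky_slope = 0.01,
                         norm = c("layer", "none"),
                         use_attention = TRUE,
                         attention_heads = 4L,
                         linear_layers = 1L,
                         fc_hidden = 32L,
                         dropout = 0,
                         num_classes = 2L) {
  norm <- match.arg(norm)
  cfg <- list(conv_channels = as.integer(conv_channels),
              kernel_size = as.integer(kernel_size),
              leaky_slope = leaky_slope, norm = norm,
              use_attention = isTRUE(use_attention),
              attention_heads = as.integer(attention_heads),
              linear_layers = as.integer(linear_layers),
              fc_hidden = as.integer(fc_hidden),
              dropout = dropout, num_classes = as.integer(num_classes))
  stopifnot(length(cfg$conv_channels) >= 1L, all(cfg$conv_channels >= 1L),
            cfg$kernel_size >= 1L, cfg$kernel_size %% 2L == 1L,
            cfg$attention_heads >= 1L, cfg$linear_layers >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$num_classes == 2L)
  width <- cfg$conv_channels[length(cfg$conv_channels)]
  if (cfg$use_attention && width %% cfg$attention_heads != 0L) {
    stop("attention_heads (", cfg$attention_heads,
         ") must divide the final convolution width (", width, ")")
  }
  class(cfg) <- "bsj_model_config"
  cfg
}

#' Initialize model parameters
#'
#' Seeded uniform fan-in initialization: every weight matrix is drawn from
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; biases start at zero,
#' normalization scales at one.
#'
#' @param config A [model_config()].
#' @param input_dim Embedding dimension `D` of the input matrices.
#' @param seed Integer seed; the same (config, input_dim, seed) triple
#'   always yields bit-identical parameters.
#' @return Nested parameter list (`conv`, `att`, `fc`).
#' @export
init_model_params <- function(config, input_dim, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  k <- config$kernel_size
  fan_unif <- function(nr, nc) {
    bound <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
  }
  conv <- list()
  cin <- input_dim
  for (l in seq_along(config$conv_channels)) {
    cout <- config$conv_channels[l]
    layer <- list(W = fan_unif(k * cin, cout), b = numeric(cout))
    if (config$norm == "layer") {
      layer$gamma <- rep(1, cout)
      layer$beta <- numeric(cout)
    }
    conv[[l]] <- layer
    cin <- cout
  }
  params <- list(conv = conv)
  if (config$use_attention) {
    params$att <- list(W_Q = fan_unif(cin, cin), W_K = fan_unif(cin, cin),
                       W_V = fan_unif(cin, cin))
  }
  widths <- c(cin, rep(config$fc_hidden, config$linear_layers - 1L),
              config$num_classes)
  params$fc <- lapply(seq_len(config$linear_layers), function(l) {
    list(W = t(fan_unif(widths[l], widths[l + 1L])),
         b = numeric(widths[l + 1L]))
  })
  params
}

# ---- elementary blocks ----------------------------------------------------

# P x C -> P x (k*C) patch matrix with symmetric zero padding.
im2col <- function(X, k) {
  p <- (k - 1L) %/% 2L
  P <- nrow(X)
  C <- ncol(X)
  if (p == 0L) return(X)
  Xpad <- rbind(matrix(0, p, C), X, matrix(0, p, C))
  do.call(cbind, lapply(0:(k - 1L), function(o) Xpad[(1:P) + o, , drop = FALSE]))
}

# Adjoint of im2col: fold a P x (k*C) gradient back to P x C.
col2im <- function(dCols, P, C, k) {
  p <- (k - 1L) %/% 2L
  if (p == 0L) return(dCols)
  dXpad <- matrix(0, P + 2L * p, C)
  for (o in 0:(k - 1L)) {
    dXpad[(1:P) + o, ] <- dXpad[(1:P) + o, ] +
      dCols[, (o * C + 1L):((o + 1L) * C), drop = FALSE]
  }
  dXpad[(p + 1L):(p + P), , drop = FALSE]
}

leaky_relu <- function(x, slope) x * (slope + (1 - slope) * (x > 0))

# Derivative of LeakyReLU w.r.t. its pre-activation, elementwise.
leaky_grad <- function(x, slope) slope + (1 - slope) * (x > 0)

row_softmax <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

LN_EPS <- 1e-5

# ---- public forward operations -------------------------------------------

#' Convolution module forward pass
#'
#' Applies every configured block of (1-D convolution along positions,
#' per-position channel normalization, LeakyReLU). Symmetric zero padding
#' preserves the position count.
#'
#' @param x `(L+2) x D` embedding matrix.
#' @param params Parameter list from [init_model_params()].
#' @param config A [model_config()].
#' @return Positions-by-channels feature matrix.
#' @export
conv_forward <- function(x, params, config) {
  conv_forward_cached(x, params$conv, config)$out
}

conv_forward_cached <- function(x, conv_params, config) {
  caches <- vector("list", length(conv_params))
  A <- x
  for (l in seq_along(conv_params)) {
    pl <- conv_params[[l]]
    cols <- im2col(A, config$kernel_size)
    Z <- sweep(cols %*% pl$W, 2L, pl$b, "+")
    if (config$norm == "layer") {
      mu <- rowMeans(Z)
      xc <- Z - mu
      v <- rowMeans(xc * xc)
      inv <- 1 / sqrt(v + LN_EPS)
      Zh <- xc * inv
      N <- sweep(sweep(Zh, 2L, pl$gamma, "*"), 2L, pl$beta, "+")
    } else {
      Zh <- NULL
      inv <- NULL
      N <- Z
    }
    A_new <- leaky_relu(N, config$leaky_slope)
    caches[[l]] <- list(cols = cols, Zh = Zh, inv = inv, N = N,
                        in_dim = ncol(A), in_rows = nrow(A))
    A <- A_new
  }
  list(out = A, caches = caches)
}

#' Scaled dot-product self-attention
#'
#' Maps the convolution features to queries, keys and values through
#' independent linear transformations (`Q = X W_Q`, `K = X W_K`,
#' `V = X W_V`), computes row-stochastic attention weights
#' `softmax(Q K' / sqrt(D_k))` and returns their product with `V`. With
#' `heads > 1` the width is split into equal slices, attended
#' independently, and concatenated.
#'
#' @param X Positions-by-channels feature matrix.
#' @param params List with `W_Q`, `W_K`, `W_V` (square, width x width).
#' @param heads Number of attention heads (must divide the width).
#' @return List with `output` (same shape as `X W_V`) and `weights`, a list
#'   of per-head attention matrices, each row summing to 1.
#' @export
self_attention <- function(X, params, heads = 1L) {
  res <- attention_cached(X, params, heads)
  list(output = res$out, weights = res$A)
}

attention_cached <- function(X, params, heads) {
  C <- ncol(params$W_Q)
  stopifnot(C %% heads == 0L)
  dh <- C %/% heads
  Q <- X %*% params$W_Q
  K <- X %*% params$W_K
  V <- X %*% params$W_V
  out <- matrix(0, nrow(X), C)
  A_list <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    A <- row_softmax(S)
    out[, cols] <- A %*% V[, cols, drop = FALSE]
    A_list[[h]] <- A
  }
  list(out = out, A = A_list, Q = Q, K = K, V = V, X = X, dh = dh)
}

#' Adaptive max pooling over positions
#'
#' Global maximum pooling with adaptive output size 1: component `j` of the
#' result is the maximum of column `j` over all positions, collapsing the
#' sequence axis to a single feature vector.
#'
#' @param X Positions-by-channels feature matrix.
#' @return Numeric vector of column maxima (length = channel count).
#' @export
adaptive_max_pool <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty input to adaptive_max_pool")
  apply(X, 2L, max)
}

#' Fully connected classifier forward pass
#'
#' Maps the pooled feature vector to class logits `z = W y + b`. With more
#' than one configured linear layer, hidden layers are interleaved with
#' LeakyReLU; the final layer always emits `num_classes` logits.
#'
#' @param Y Pooled feature vector.
#' @param params Parameter list from [init_model_params()] (uses `$fc`).
#' @param config A [model_config()].
#' @return Numeric logit vector of length `num_classes`.
#' @export
fc_forward <- function(Y, params, config) {
  fc_forward_cached(Y, params$fc, config)$z
}

fc_forward_cached <- function(Y, fc_params, config) {
  nl <- length(fc_params)
  acts <- vector("list", nl + 1L)
  pre <- vector("list", nl)
  acts[[1L]] <- as.numeric(Y)
  for (l in seq_len(nl)) {
    z <- drop(fc_params[[l]]$W %*% acts[[l]]) + fc_params[[l]]$b
    pre[[l]] <- z
    acts[[l + 1L]] <- if (l < nl) leaky_relu(z, config$leaky_slope) else z
  }
  list(z = acts[[nl + 1L]], acts = acts, pre = pre)
}

#' Numerically stable softmax
#'
#' `softmax(z)_i = exp(z_i) / sum_j exp(z_j)`, computed after subtracting
#' the maximum logit.
#'
#' @param z Finite numeric logit vector.
#' @return Probability vector summing to 1.
#' @export
softmax_probs <- function(z) {
  stopifnot(all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}

#' Cross-entropy loss
#'
#' `L = -sum_i y_i log(p_i)` with one-hot true labels, i.e. `-log p_true`;
#' for a batch (matrix of probabilities, vector of labels) the mean over
#' examples is returned. Probabilities are clamped at `eps` before the log
#' so a confidently wrong prediction yields a large finite loss.
#'
#' @param probs Probability vector (length `C`) or `n x C` matrix.
#' @param y True class label(s) in `{0, 1}` (0 = negative/lncRNA,
#'   1 = positive/circRNA).
#' @param eps Clamp floor for the log (default `1e-12`).
#' @return Scalar mean loss.
#' @export
cross_entropy <- function(probs, y, eps = 1e-12) {
  if (is.matrix(probs)) {
    stopifnot(length(y) == nrow(probs))
    p_true <- probs[cbind(seq_len(nrow(probs)), y + 1L)]
  } else {
    stopifnot(length(y) == 1L)
    p_true <- probs[y + 1L]
  }
  stopifnot(all(y %in% c(0L, 1L)))
  mean(-log(pmax(p_true, eps)))
}

#' Full classifier forward pass
#'
#' Composes convolution module, self-attention (unless ablated), adaptive
#' max pooling, fully connected layer and softmax.
#'
#' @param x `(L+2) x D` embedding matrix.
#' @param params Parameters from [init_model_params()].
#' @param config A [model_config()].
#' @return List with `probs` (length-2 probability vector: `P(lncRNA)`,
#'   `P(circRNA)`), `logits`, and `pooled`.
#' @export
model_forward <- function(x, params, config) {
  fw <- nn_forward(x, params, config, dropout_mask = NULL)
  list(probs = fw$probs, logits = fw$z, pooled = fw$pooled)
}

# Forward pass retaining every intermediate needed for backprop.
nn_forward <- function(x, params, config, dropout_mask = NULL) {
  conv <- conv_forward_cached(x, params$conv, config)
  if (config$use_attention) {
    att <- attention_cached(conv$out, params$att, config$attention_heads)
    feat <- att$out
  } else {
    att <- NULL
    feat <- conv$out
  }
  pool_idx <- max.col(t(feat), ties.method = "first")
  pooled <- feat[cbind(pool_idx, seq_len(ncol(feat)))]
  pooled_in <- if (is.null(dropout_mask)) pooled else pooled * dropout_mask
  fc <- fc_forward_cached(pooled_in, params$fc, config)
  probs <- softmax_probs(fc$z)
  list(x = x, conv = conv, att = att, feat = feat, pool_idx = pool_idx,
       pooled = pooled, dropout_mask = dropout_mask, fc = fc,
       z = fc$z, probs = probs)
}

# Backward pass for mean cross-entropy of a single example.
# Returns gradients in the same nested structure as the parameters.
nn_backward <- function(fw, params, config, y) {
  grads <- list()
  # softmax + cross-entropy
  dz <- fw$probs
  dz[y + 1L] <- dz[y + 1L] - 1
  # fully connected stack
  fc_params <- params$fc
  nl <- length(fc_params)
  fc_grads <- vector("list", nl)
  d <- dz
  for (l in rev(seq_len(nl))) {
    a_prev <- fw$fc$acts[[l]]
    fc_grads[[l]] <- list(W = outer(d, a_prev), b = d)
    if (l > 1L) {
      da <- drop(t(fc_params[[l]]$W) %*% d)
      zp <- fw$fc$pre[[l - 1L]]
      d <- da * leaky_grad(zp, config$leaky_slope)
    } else {
      d <- drop(t(fc_params[[l]]$W) %*% d)
    }
  }
  grads$fc <- fc_grads
  dpooled_in <- d
  dpooled <- if (is.null(fw$dropout_mask)) dpooled_in else dpooled_in * fw$dropout_mask
  # max pool: route each channel's gradient to its argmax position
  dfeat <- matrix(0, nrow(fw$feat), ncol(fw$feat))
  dfeat[cbind(fw$pool_idx, seq_len(ncol(fw$feat)))] <- dpooled
  # attention
  if (config$use_attention) {
    att <- fw$att
    X <- att$X
    dh <- att$dh
    heads <- config$attention_heads
    dQ <- matrix(0, nrow(X), ncol(att$Q))
    dK <- dQ
    dV <- dQ
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- att$A[[h]]
      dOh <- dfeat[, cols, drop = FALSE]
      Vh <- att$V[, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% att$K[, cols, drop = FALSE]) / sqrt(dh)
      dK[, cols] <- (t(dS) %*% att$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    grads$att <- list(W_Q = t(X) %*% dQ, W_K = t(X) %*% dK, W_V = t(X) %*% dV)
    dconv_out <- dQ %*% t(params$att$W_Q) + dK %*% t(params$att$W_K) +
      dV %*% t(params$att$W_V)
  } else {
    dconv_out <- dfeat
  }
  # convolution stack
  conv_params <- params$conv
  caches <- fw$conv$caches
  conv_grads <- vector("list", length(conv_params))
  dA <- dconv_out
  for (l in rev(seq_along(conv_params))) {
    ch <- caches[[l]]
    pl <- conv_params[[l]]
    dN <- dA * leaky_grad(ch$N, config$leaky_slope)
    if (config$norm == "layer") {
      dgamma <- colSums(dN * ch$Zh)
      dbeta <- colSums(dN)
      dZh <- sweep(dN, 2L, pl$gamma, "*")
      m1 <- rowMeans(dZh)
      m2 <- rowMeans(dZh * ch$Zh)
      dZ <- (dZh - m1 - ch$Zh * m2) * ch$inv
    } else {
      dZ <- dN
    }
    gW <- t(ch$cols) %*% dZ
    gb <- colSums(dZ)
    dcols <- dZ %*% t(pl$W)
    dA <- col2im(dcols, ch$in_rows, ch$in_dim, config$kernel_size)
    g <- list(W = gW, b = gb)
    if (config$norm == "layer") {
      g$gamma <- dgamma
      g$beta <- dbeta
    }
    conv_grads[[l]] <- g
  }
  grads$conv <- conv_grads
  grads[names(params)]
}

# ---- parameter-tree utilities ---------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

zeros_like <- function(params) tree_map(function(p) p * 0, params)

#' Save a self-describing model checkpoint
#'
#' The checkpoint bundles everything needed to reload and apply the model:
#' parameters, model configuration, training configuration, the embedder
#' identifier the model was trained with, the flank width, and the seed.
#'
#' @param params Trained parameters.
#' @param config A [model_config()].
#' @param train_config A [train_config()].
#' @param embedder_id Identifier of the embedder used in training.
#' @param path Output path.
#' @param flank_len Flank width the features were extracted with.
#' @param input_dim Embedding dimension.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, config, train_config, embedder_id, path,
                            flank_len = 50L, input_dim = NULL) {
  ckpt <- list(params = params, config = config, train_config = train_config,
               embedder_id = embedder_id, flank_len = as.integer(flank_len),
               input_dim = input_dim, format_version = 1L)
  saveRDS(ckpt, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The checkpoint list.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ckpt <- readRDS(path)
  stopifnot(is.list(ckpt), !is.null(ckpt$params), !is.null(ckpt$config))
  ckpt
}
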