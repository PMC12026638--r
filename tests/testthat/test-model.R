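# Literal per-element implementation of scaled dot-product attention,
# kept deliberately naive (triple loops) as an independent oracle.
attention_oracle <- function(X, W_Q, W_K, W_V, heads = 1L) {
  C <- ncol(W_Q)
  dh <- C / heads
  P <- nrow(X)
  Q <- X %*% W_Q
  K <- X %*% W_K
  V <- X %*% W_V
  out <- matrix(0, P, C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(P)) {
      scores <- numeric(P)
      for (j in seq_len(P)) {
        scores[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
      }
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      for (c in cols) {
        out[i, c] <- sum(w * V[, c])
      }
    }
  }
  out
}

test_that("convolution module preserves the position count", {
  cfg <- tiny_config()
  params <- init_model_params(cfg, 5L, seed = 2)
  x <- matrix(rnorm(202 * 5), 202, 5)
  out <- conv_forward(x, params, cfg)
  expect_equal(nrow(out), 202L)
  expect_equal(ncol(out), 6L)
  expect_true(all(is.finite(out)))
})

test_that("an identity convolution with normalization disabled reproduces its input", {
  cfg <- model_config(conv_channels = 3L, norm = "none", use_attention = FALSE,
                      kernel_size = 3L)
  # kernel = [zero | identity | zero] picks out the centre position
  W <- rbind(matrix(0, 3, 3), diag(3), matrix(0, 3, 3))
  params <- list(conv = list(list(W = W, b = numeric(3))))
  x <- matrix(runif(30, 0.1, 2), 10, 3)    # positive, so LeakyReLU is identity
  expect_equal(conv_forward(x, params, cfg), x, tolerance = 1e-12)
})

test_that("LeakyReLU multiplies negative inputs by the configured slope", {
  expect_equal(circbsj:::leaky_relu(-1, 0.01), -0.01)
  expect_equal(circbsj:::leaky_relu(2, 0.01), 2)
  expect_equal(circbsj:::leaky_relu(c(-3, 0, 3), 0.2), c(-0.6, 0, 3))
})

test_that("self-attention over a single position returns that position's values", {
  X <- matrix(c(1, 2, 3), 1, 3)
  I3 <- diag(3)
  res <- self_attention(X, list(W_Q = I3, W_K = I3, W_V = I3), heads = 1L)
  expect_equal(res$output, X)              # softmax over one key is 1
  expect_equal(res$weights[[1]], matrix(1, 1, 1))
})

test_that("attention weights are row-stochastic for random inputs", {
  set.seed(8)
  for (i in 1:10) {
    P <- sample(2:12, 1)
    C <- 4L
    X <- matrix(rnorm(P * C), P, C)
    params <- list(W_Q = matrix(rnorm(16), 4), W_K = matrix(rnorm(16), 4),
                   W_V = matrix(rnorm(16), 4))
    heads <- sample(c(1L, 2L), 1)
    res <- self_attention(X, params, heads = heads)
    for (A in res$weights) {
      expect_equal(rowSums(A), rep(1, P), tolerance = 1e-6)
      expect_true(all(A >= 0))
    }
  }
})

test_that("self-attention matches the literal element-wise oracle", {
  set.seed(13)
  for (i in 1:12) {
    P <- sample(1:4, 1)
    C <- 4L
    X <- matrix(rnorm(P * C), P, C)
    params <- list(W_Q = matrix(rnorm(C * C), C), W_K = matrix(rnorm(C * C), C),
                   W_V = matrix(rnorm(C * C), C))
    heads <- sample(c(1L, 2L), 1)
    got <- self_attention(X, params, heads = heads)$output
    want <- attention_oracle(X, params$W_Q, params$W_K, params$W_V, heads)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # the 2-position, 2-dim identity-weight case, expanded by hand:
  # scores s_ij = <x_i, x_j>/sqrt(2); rows softmaxed then times X
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  I2 <- diag(2)
  got <- self_attention(X, list(W_Q = I2, W_K = I2, W_V = I2))$output
  a <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + exp(0))
  want <- matrix(c(a, 1 - a, 1 - a, a), 2, 2)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("adaptive max pooling takes column maxima and ignores row order", {
  expect_equal(adaptive_max_pool(matrix(c(1, 3, 5, 2), 2)), c(3, 5))
  expect_equal(adaptive_max_pool(matrix(7, 4, 3)), rep(7, 3))
  set.seed(21)
  X <- matrix(rnorm(40), 8, 5)
  expect_equal(adaptive_max_pool(X), adaptive_max_pool(X[sample(8), ]))
  expect_equal(adaptive_max_pool(X), apply(X, 2, max))
  expect_error(adaptive_max_pool(matrix(numeric(), 0, 3)), "empty")
})

test_that("the fully connected stack maps pooled features to two logits", {
  cfg <- model_config(conv_channels = 4L, linear_layers = 1L)
  params <- list(fc = list(list(W = matrix(0, 2, 4), b = c(1, -1))))
  expect_equal(fc_forward(c(1, 2, 3, 4), params, cfg), c(1, -1))

  W <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- c(0.5, -0.5)
  params <- list(fc = list(list(W = W, b = b)))
  y <- c(2, -1)
  expect_equal(fc_forward(y, params, model_config(conv_channels = 2L)),
               drop(W %*% y) + b)

  # three linear layers still emit two logits
  cfg3 <- model_config(conv_channels = 6L, linear_layers = 3L, fc_hidden = 5L,
                       attention_heads = 2L)
  params3 <- init_model_params(cfg3, 4L, seed = 3)
  z <- fc_forward(rnorm(6), params3, cfg3)
  expect_length(z, 2L)
})

test_that("softmax has its closed-form values and normalizes", {
  expect_equal(softmax_probs(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_probs(c(log(3), 0)), c(0.75, 0.25))
  expect_equal(softmax_probs(c(1000, 1000)), c(0.5, 0.5))  # stable at large z
  set.seed(4)
  for (i in 1:20) {
    p <- softmax_probs(rnorm(2, sd = 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("cross-entropy matches -log p_true and is clamped at zero probability", {
  expect_equal(cross_entropy(c(0, 1), 1L), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), 0L), log(2))
  set.seed(6)
  for (i in 1:20) {
    p1 <- runif(1, 0.01, 0.99)
    y <- sample(0:1, 1)
    expect_equal(cross_entropy(c(1 - p1, p1), y),
                 -log(c(1 - p1, p1)[y + 1]))
  }
  # batched mean
  P <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy(P, c(0L, 1L)),
               mean(c(log(2), -log(0.75))))
  # clamped, not infinite
  expect_lt(cross_entropy(c(1, 0), 1L), 30)
  expect_true(is.finite(cross_entropy(c(1, 0), 1L)))
})

test_that("the full forward pass composes and respects the ablation toggle", {
  x <- matrix(rnorm(52 * 4), 52, 4)
  for (use_att in c(TRUE, FALSE)) {
    cfg <- tiny_config(use_attention = use_att)
    params <- init_model_params(cfg, 4L, seed = 5)
    out <- model_forward(x, params, cfg)
    expect_length(out$probs, 2L)
    expect_equal(sum(out$probs), 1, tolerance = 1e-6)
    expect_length(out$pooled, 6L)
  }
})

test_that("forward passes are bit-identical across runs with the same seed", {
  x <- matrix(rnorm(30 * 4), 30, 4)
  cfg <- tiny_config()
  p1 <- init_model_params(cfg, 4L, seed = 42)
  p2 <- init_model_params(cfg, 4L, seed = 42)
  expect_identical(p1, p2)
  expect_identical(model_forward(x, p1, cfg)$probs,
                   model_forward(x, p2, cfg)$probs)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(17)
  cfg <- model_config(conv_channels = c(6L, 4L), attention_heads = 2L,
                      linear_layers = 2L, fc_hidden = 5L)
  x <- matrix(rnorm(12 * 3), 12, 3)
  params <- init_model_params(cfg, 3L, seed = 7)
  y <- 1L
  fw <- circbsj:::nn_forward(x, params, cfg)
  g <- circbsj:::nn_backward(fw, params, cfg, y)
  loss_fn <- function(p) cross_entropy(model_forward(x, p, cfg)$probs, y)
  eps <- 1e-6
  # one scalar from each parameter family
  probes <- list(
    list(c("conv", 1L, "W"), 5L), list(c("conv", 1L, "gamma"), 2L),
    list(c("conv", 2L, "b"), 1L), list(c("conv", 2L, "beta"), 3L),
    list(c("att", NA, "W_Q"), 3L), list(c("att", NA, "W_K"), 7L),
    list(c("att", NA, "W_V"), 11L),
    list(c("fc", 1L, "W"), 3L), list(c("fc", 2L, "b"), 2L))
  for (pr in probes) {
    path <- pr[[1]]
    idx <- pr[[2]]
    bump <- function(delta) {
      p <- params
      if (is.na(path[2])) {
        p[[path[1]]][[path[3]]][idx] <- p[[path[1]]][[path[3]]][idx] + delta
      } else {
        l <- as.integer(path[2])
        p[[path[1]]][[l]][[path[3]]][idx] <- p[[path[1]]][[l]][[path[3]]][idx] + delta
      }
      p
    }
    num <- (loss_fn(bump(eps)) - loss_fn(bump(-eps))) / (2 * eps)
    ana <- if (is.na(path[2])) {
      g[[path[1]]][[path[3]]][idx]
    } else {
      g[[path[1]]][[as.integer(path[2])]][[path[3]]][idx]
    }
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste("gradient at", paste(path, collapse = "$")))
  }
})

test_that("loss decreases over the first training steps on a separable batch", {
  sep <- generate_separable_embeddings(10, dim = 6, margin = 8, seed = 3,
                                       n_positions = 8)
  cfg <- model_config(conv_channels = c(6L, 4L), attention_heads = 2L)
  tc <- train_config(epochs = 10L, batch_size = 20L, seed = 1L)
  fit <- train(sep$embeddings, sep$y, cfg, tc)
  expect_lt(fit$history$train_loss[10], fit$history$train_loss[1])
})

test_that("checkpoints are self-describing and round-trip", {
  cfg <- tiny_config()
  params <- init_model_params(cfg, 4L, seed = 1)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(params, cfg, train_config(), "one_hot", f, flank_len = 50L,
                  input_dim = 4L)
  ck <- load_checkpoint(f)
  expect_identical(ck$params, params)
  expect_identical(ck$embedder_id, "one_hot")
  expect_equal(ck$flank_len, 50L)
  expect_identical(ck$config, cfg)
  expect_error(load_checkpoint(tempfile()), "not found")
})
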