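#' Training configuration
#'
#' @param learning_rate Optimizer step size (default 0.005).
#' @param epochs Maximum number of passes over the training set.
#' @param batch_size Minibatch size (default 64).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Integer seed controlling parameter initialization and data
#'   order; fixes the whole run bit-for-bit on CPU.
#' @param early_stop_patience Stop after this many epochs without a new
#'   best validation loss (ignored when no validation set is supplied).
#' @param class_weights Optional length-2 vector of loss weights for
#'   classes (negative, positive); `NULL` (default) weights all examples
#'   equally, `"balanced"` uses inverse class frequencies.
#' @return A list of class `bsj_train_config`.
#' @export
train_config <- function(learning_rate = 0.005, epochs = 20L, batch_size = 64L,
                         optimizer = c("adam", "sgd"), seed = 1L,
                         early_stop_patience = 5L, class_weights = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 class_weights = class_weights),
            class = "bsj_train_config")
}

#' Train the junction classifier
#'
#' Minimizes mean cross-entropy with minibatch Adam (or SGD). The run is
#' fully deterministic given `tc$seed`: initialization, shuffling and any
#' dropout masks all derive from it. When a validation set is supplied the
#' parameters with the best validation loss are returned and training stops
#' early after `early_stop_patience` stale epochs; otherwise the final
#' parameters are returned.
#'
#' @param embeddings List of `(L+2) x D` embedding matrices (training set).
#' @param y Integer labels in `{0, 1}`, one per training embedding.
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param val_embeddings,val_y Optional validation set.
#' @param verbose Print one line per epoch.
#' @return List with `params` (trained), `history` (per-epoch data.frame
#'   with train loss, validation loss/accuracy), `config`, `tc`, and
#'   `best_epoch`.
#' @export
train <- function(embeddings, y, config, tc = train_config(),
                  val_embeddings = NULL, val_y = NULL, verbose = FALSE) {
  stopifnot(length(embeddings) >= 1L, length(embeddings) == length(y),
            all(y %in% c(0L, 1L)))
  has_val <- !is.null(val_embeddings) && length(val_embeddings) > 0L
  input_dim <- ncol(embeddings[[1L]])
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(tc$seed)
  params <- init_model_params(config, input_dim, seed = tc$seed)
  w <- example_weights(y, tc$class_weights)

  opt_state <- list(m = zeros_like(params), v = zeros_like(params), t = 0L)
  n <- length(embeddings)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stale <- 0L

  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (bstart in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[bstart:min(bstart + tc$batch_size - 1L, n)]
      gsum <- NULL
      wsum <- 0
      bloss <- 0
      for (i in idx) {
        mask <- if (config$dropout > 0) {
          (stats::runif(config$conv_channels[length(config$conv_channels)]) >
             config$dropout) / (1 - config$dropout)
        }
        fw <- tryCatch(
          nn_forward(embeddings[[i]], params, config, dropout_mask = mask),
          error = function(e) {
            stop("training diverged: non-finite values at epoch ", epoch,
                 ", example ", i, " (", conditionMessage(e), ")", call. = FALSE)
          })
        li <- -log(max(fw$probs[y[i] + 1L], 1e-12))
        if (!is.finite(li)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               ", example ", i)
        }
        bloss <- bloss + w[i] * li
        g <- nn_backward(fw, params, config, y[i])
        g <- tree_map(function(x) w[i] * x, g)
        gsum <- if (is.null(gsum)) g else tree_map(`+`, gsum, g)
        wsum <- wsum + w[i]
      }
      grads <- tree_map(function(x) x / wsum, gsum)
      epoch_loss <- epoch_loss + bloss
      if (tc$optimizer == "adam") {
        opt_state$t <- opt_state$t + 1L
        b1 <- 0.9
        b2 <- 0.999
        opt_state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g,
                                opt_state$m, grads)
        opt_state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g * g,
                                opt_state$v, grads)
        t <- opt_state$t
        lr <- tc$learning_rate
        params <- tree_map(function(p, m, v) {
          p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + 1e-8)
        }, params, opt_state$m, opt_state$v)
      } else {
        params <- tree_map(function(p, g) p - tc$learning_rate * g,
                           params, grads)
      }
    }
    train_loss <- epoch_loss / sum(w)
    if (has_val) {
      vl <- batch_loss(params, config, val_embeddings, val_y)
      va <- mean(predict_labels(params, config, val_embeddings) == val_y)
    } else {
      vl <- NA_real_
      va <- NA_real_
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = vl, val_accuracy = va))
    if (verbose) {
      message(sprintf("epoch %3d  train_loss %.4f  val_loss %s", epoch,
                      train_loss, ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
    }
    if (has_val) {
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_params <- params
        best_epoch <- epoch
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= tc$early_stop_patience) break
      }
    } else {
      best_params <- params
      best_epoch <- epoch
    }
  }
  list(params = best_params, history = history, config = config, tc = tc,
       best_epoch = best_epoch)
}

example_weights <- function(y, class_weights) {
  if (is.null(class_weights)) return(rep(1, length(y)))
  if (identical(class_weights, "balanced")) {
    tab <- table(factor(y, levels = c(0L, 1L)))
    cw <- as.numeric(length(y) / (2 * pmax(tab, 1L)))
  } else {
    stopifnot(is.numeric(class_weights), length(class_weights) == 2L)
    cw <- class_weights
  }
  cw[y + 1L]
}

batch_loss <- function(params, config, embeddings, y) {
  probs <- t(vapply(embeddings, function(e) model_forward(e, params, config)$probs,
                    numeric(2L)))
  cross_entropy(probs, y)
}

predict_labels <- function(params, config, embeddings) {
  vapply(embeddings, function(e) {
    which.max(model_forward(e, params, config)$probs) - 1L
  }, integer(1L))
}

#' Predict classes and probabilities for embedded sequences
#'
#' @param params Trained parameters.
#' @param config A [model_config()].
#' @param embeddings List of embedding matrices.
#' @return A data.frame with one row per input, in input order: `label`
#'   (argmax class, 1 = circRNA), `prob_lncRNA`, `prob_circRNA`.
#' @export
predict_classes <- function(params, config, embeddings) {
  if (length(embeddings) == 0L) {
    return(data.frame(label = integer(), prob_lncRNA = numeric(),
                      prob_circRNA = numeric()))
  }
  probs <- t(vapply(embeddings, function(e) model_forward(e, params, config)$probs,
                    numeric(2L)))
  data.frame(label = max.col(probs, ties.method = "first") - 1L,
             prob_lncRNA = probs[, 1L], prob_circRNA = probs[, 2L])
}

#' Predict from feature sequences through an embedder
#'
#' Inference entry point: embeds each feature sequence with the supplied
#' embedder (which must match the checkpoint's embedder) and applies the
#' trained classifier.
#'
#' @param ckpt Checkpoint list from [load_checkpoint()].
#' @param sequences Character vector of feature sequences.
#' @param emb A `bsj_embedder` whose `id` matches `ckpt$embedder_id`.
#' @return Data.frame as in [predict_classes()], in input order.
#' @export
predict_sequences <- function(ckpt, sequences, emb) {
  if (!identical(emb$id, ckpt$embedder_id)) {
    stop("embedder mismatch: checkpoint was trained with '", ckpt$embedder_id,
         "' but '", emb$id, "' was supplied")
  }
  predict_classes(ckpt$params, ckpt$config, embed_all(emb, sequences))
}

#' Evaluate a trained classifier
#'
#' Predicts with the argmax rule, accumulates a confusion table (positive
#' class = circRNA = 1), and derives metrics.
#'
#' @param params Trained parameters.
#' @param config A [model_config()].
#' @param embeddings List of embedding matrices (test set).
#' @param y True labels in `{0, 1}`.
#' @return List with `confusion` (tp, fp, tn, fn) and `metrics`
#'   (see [compute_metrics()]).
#' @export
evaluate <- function(params, config, embeddings, y) {
  stopifnot(length(embeddings) >= 1L, length(embeddings) == length(y))
  pred <- predict_labels(params, config, embeddings)
  ct <- confusion_table(pred, y)
  list(confusion = ct, metrics = compute_metrics(ct))
}

#' Build a confusion table from predictions
#'
#' @param pred,truth Integer vectors in `{0, 1}`; class 1 (circRNA) is the
#'   positive class.
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_table <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  list(tp = sum(pred == 1L & truth == 1L),
       fp = sum(pred == 1L & truth == 0L),
       tn = sum(pred == 0L & truth == 0L),
       fn = sum(pred == 0L & truth == 1L))
}

#' Binary classification metrics from a confusion table
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, recall (sensitivity)
#' `tp/(tp+fn)`, F1 (their harmonic mean), and the Matthews correlation
#' coefficient `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' A metric whose denominator is zero is reported as 0 with a warning.
#'
#' @param ct Confusion table: list or named vector with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `mcc`.
#' @export
compute_metrics <- function(ct) {
  tp <- as.numeric(ct$tp)
  fp <- as.numeric(ct$fp)
  tn <- as.numeric(ct$tn)
  fn <- as.numeric(ct$fn)
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0", call. = FALSE)
      0
    } else {
      num / den
    }
  }
  accuracy <- (tp + tn) / total
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined (zero denominator); reporting 0", call. = FALSE)
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    warning("mcc undefined (zero denominator); reporting 0", call. = FALSE)
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, mcc = mcc)
}
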