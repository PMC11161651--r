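#' @useDynLib ecgxai, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ECG_CLASSES <- c("non-AF", "AF")
BN_EPS <- 1e-5

#' Instantiate a trainable CNN from a specification
#'
#' Builds the network described by a [cnn_spec()]: a stack of strided 1D
#' convolutions, each followed by batch normalization (optional) and ReLU,
#' a global-average-pooling head and a dense softmax layer of size two.
#' Weights use seeded He-normal initialization, so two builds with the same
#' seed are identical. Thanks to global average pooling the model accepts
#' padded signals of any length at least `spec$r`.
#'
#' @param spec A `cnn_spec`.
#' @param f_last Feature maps in the last convolutional layer; overrides
#'   the value stored in `spec` (the 4x/2x/1x schedule is re-derived).
#' @param seed Integer seed for weight initialization.
#' @param use_bias Include convolution biases (disable for strictly
#'   bias-free networks, e.g. when checking relevance conservation).
#' @return An object of class `ecg_cnn`.
#' @export
build_model <- function(spec, f_last = spec$f_last, seed = 1, use_bias = TRUE) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (f_last != spec$f_last)
    spec <- cnn_spec(spec$layers$kernel, spec$layers$stride, f_last = f_last,
                     batch_norm = spec$layers$batch_norm[1])
  with_seed(seed, {
    L <- spec$n_layers
    cin <- 1L
    conv <- vector("list", L)
    for (l in seq_len(L)) {
      k <- spec$layers$kernel[l]
      cout <- spec$layers$feature_maps[l]
      fan_in <- cin * k
      conv[[l]] <- list(
        W = matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in),
        b = numeric(cout),
        k = k, s = spec$layers$stride[l], cin = cin, cout = cout,
        bn = if (spec$layers$batch_norm[l])
          list(gamma = rep(1, cout), beta = numeric(cout),
               rmean = numeric(cout), rvar = rep(1, cout)) else NULL)
      cin <- cout
    }
    dense <- list(W = matrix(stats::rnorm(2 * cin, 0, sqrt(1 / cin)), 2, cin),
                  b = numeric(2))
    structure(list(spec = spec, conv = conv, dense = dense,
                   classes = ECG_CLASSES, use_bias = use_bias,
                   seed = as.integer(seed %% .Machine$integer.max)),
              class = "ecg_cnn")
  })
}

#' @export
print.ecg_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$conv, function(cv)
    length(cv$W) + length(cv$b) + if (!is.null(cv$bn)) 2 * cv$cout else 0,
    numeric(1))) + length(x$dense$W) + 2
  cat(sprintf("<ecg_cnn> receptive field %d, %d conv layers, %d parameters\n",
              x$spec$r, x$spec$n_layers, n_par))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass. X: cube (1 x L x B) of padded signals.
# In training mode batch statistics are used for normalization and the
# returned model carries updated running statistics.
cnn_forward <- function(model, X, train = FALSE, keep = FALSE,
                        bn_momentum = 0.9) {
  acts <- if (keep) vector("list", length(model$conv)) else NULL
  A <- X
  for (l in seq_along(model$conv)) {
    cv <- model$conv[[l]]
    A_in <- A
    Z <- conv1d_fwd(A, cv$W, if (model$use_bias) cv$b else numeric(cv$cout),
                    cv$k, cv$s)
    if (!is.null(cv$bn)) {
      if (train) {
        st <- channel_stats(Z)
        mu <- as.numeric(st$mean)
        v <- as.numeric(st$var)
        model$conv[[l]]$bn$rmean <- bn_momentum * cv$bn$rmean + (1 - bn_momentum) * mu
        model$conv[[l]]$bn$rvar <- bn_momentum * cv$bn$rvar + (1 - bn_momentum) * v
      } else {
        mu <- cv$bn$rmean
        v <- cv$bn$rvar
      }
      sd_ <- sqrt(v + BN_EPS)
      br <- bn_relu_fwd(Z, cv$bn$gamma, cv$bn$beta, mu, sd_)
      if (keep) acts[[l]] <- list(x_in = A_in, xhat = br$xhat, sd = sd_, a = br$a)
      A <- br$a
    } else {
      A <- Z * (Z > 0)
      if (keep) acts[[l]] <- list(x_in = A_in, a = A)
    }
  }
  dims <- dim(A)
  gap <- gap_fwd(A)
  logits <- t(model$dense$W %*% gap + model$dense$b)
  list(probs = softmax_rows(logits), logits = logits, gap = gap,
       lout = dims[2], acts = acts, model = model)
}

# Backward pass from d(loss)/d(logits). Needs a forward pass with
# keep = TRUE. Returns parameter gradients and the input gradient.
cnn_backward <- function(model, fw, dlogits, train = TRUE, guided = FALSE,
                         param_grads = TRUE) {
  L <- length(model$conv)
  C <- nrow(fw$gap)
  B <- ncol(fw$gap)
  dW_dense <- t(dlogits) %*% t(fw$gap)
  db_dense <- colSums(dlogits)
  dG <- t(model$dense$W) %*% t(dlogits)            # C x B
  dA <- gap_bwd(dG, fw$lout)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cv <- model$conv[[l]]
    ac <- fw$acts[[l]]
    dgamma <- dbeta <- NULL
    if (!is.null(cv$bn)) {
      sd_ <- if (train) ac$sd else sqrt(cv$bn$rvar + BN_EPS)
      br <- bn_relu_bwd(dA, ac$a, ac$xhat, cv$bn$gamma, sd_, train, guided)
      dz <- br$dz
      if (param_grads && train) {
        dgamma <- as.numeric(br$dgamma)
        dbeta <- as.numeric(br$dbeta)
      }
    } else {
      dz <- dA * (ac$a > 0)
      if (guided) dz <- dz * (dA > 0)
    }
    if (param_grads) {
      g <- conv1d_bwd(ac$x_in, dz, cv$W, cv$k, cv$s)
      grads[[l]] <- list(dW = g$dW, db = g$db, dgamma = dgamma, dbeta = dbeta)
      dA <- g$dX
    } else {
      dA <- conv1d_bwd_input(dz, cv$W, cv$cin, dim(ac$x_in)[2], cv$k, cv$s)
    }
  }
  list(conv = grads, dense = list(dW = dW_dense, db = db_dense), dX = dA)
}

records_to_cube <- function(records, pad) {
  n <- length(records[[1]]$samples)
  sig <- vapply(records, function(r) pad_signal(r$samples, pad),
                numeric(n + 2 * pad))
  array(sig, c(1, n + 2 * pad, length(records)))
}

labels_to_index <- function(labels) {
  idx <- match(labels, ECG_CLASSES)
  if (anyNA(idx)) stop("labels must be 'non-AF' or 'AF'", call. = FALSE)
  idx
}

#' Class probabilities for ECG records
#'
#' Pads each record's signal with the model's receptive field and runs the
#' network in evaluation mode (running batch-norm statistics).
#'
#' @param model An `ecg_cnn`.
#' @param records List of (preprocessed) `ecg_record`s, or a numeric cube
#'   `(1, L, B)` of already-padded signals.
#' @param chunk Records per forward chunk (memory control).
#' @return A matrix (records x 2) of class probabilities, columns
#'   `non-AF`, `AF`.
#' @export
predict_proba <- function(model, records, chunk = 64) {
  X <- if (is.array(records)) records
       else records_to_cube(records, model$spec$pad)
  B <- dim(X)[3]
  out <- matrix(NA_real_, B, 2, dimnames = list(NULL, model$classes))
  for (start in seq(1, B, by = chunk)) {
    sel <- start:min(start + chunk - 1, B)
    fw <- cnn_forward(model, X[, , sel, drop = FALSE], train = FALSE)
    out[sel, ] <- fw$probs
  }
  out
}

predict_classes <- function(probs) {
  # tie -> non-AF (conservative negative call)
  ifelse(probs[, 2] > probs[, 1], ECG_CLASSES[2], ECG_CLASSES[1])
}

cross_entropy <- function(probs, y_idx, eps = 1e-12) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], eps)))
}

#' Confusion-matrix metrics with AF as the positive class
#'
#' @param truth,pred Character vectors of labels (`"AF"` / `"non-AF"`).
#' @return List with `sensitivity`, `specificity`, `accuracy`, `f1`, all in
#'   percent.
#' @export
classification_metrics <- function(truth, pred) {
  if (length(truth) == 0) stop("no records to evaluate", call. = FALSE)
  tp <- sum(truth == "AF" & pred == "AF")
  fn <- sum(truth == "AF" & pred != "AF")
  tn <- sum(truth != "AF" & pred != "AF")
  fp <- sum(truth != "AF" & pred == "AF")
  list(sensitivity = 100 * tp / max(tp + fn, 1),
       specificity = 100 * tn / max(tn + fp, 1),
       accuracy = 100 * (tp + tn) / length(truth),
       f1 = 100 * 2 * tp / max(2 * tp + fp + fn, 1))
}

#' Evaluate a model or ensemble on labelled records
#'
#' @param object An `ecg_cnn` or `ecg_ensemble`.
#' @param records List of labelled, preprocessed `ecg_record`s.
#' @return Metrics list from [classification_metrics()].
#' @export
evaluate <- function(object, records) UseMethod("evaluate")

#' @export
evaluate.ecg_cnn <- function(object, records) {
  probs <- predict_proba(object, records)
  classification_metrics(record_labels(records), predict_classes(probs))
}

adam_init <- function(par) lapply(par, function(p) list(m = p * 0, v = p * 0))

adam_update <- function(par, grad, state, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  for (i in seq_along(par)) {
    state[[i]]$m <- b1 * state[[i]]$m + (1 - b1) * grad[[i]]
    state[[i]]$v <- b2 * state[[i]]$v + (1 - b2) * grad[[i]]^2
    mhat <- state[[i]]$m / (1 - b1^t)
    vhat <- state[[i]]$v / (1 - b2^t)
    par[[i]] <- par[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

flatten_params <- function(model) {
  out <- list()
  for (l in seq_along(model$conv)) {
    cv <- model$conv[[l]]
    out[[paste0("W", l)]] <- cv$W
    if (model$use_bias) out[[paste0("b", l)]] <- cv$b
    if (!is.null(cv$bn)) {
      out[[paste0("g", l)]] <- cv$bn$gamma
      out[[paste0("be", l)]] <- cv$bn$beta
    }
  }
  out$Wd <- model$dense$W
  out$bd <- model$dense$b
  out
}

unflatten_params <- function(model, par) {
  for (l in seq_along(model$conv)) {
    model$conv[[l]]$W <- par[[paste0("W", l)]]
    if (model$use_bias) model$conv[[l]]$b <- par[[paste0("b", l)]]
    if (!is.null(model$conv[[l]]$bn)) {
      model$conv[[l]]$bn$gamma <- par[[paste0("g", l)]]
      model$conv[[l]]$bn$beta <- par[[paste0("be", l)]]
    }
  }
  model$dense$W <- par$Wd
  model$dense$b <- par$bd
  model
}

flatten_grads <- function(model, bw) {
  out <- list()
  for (l in seq_along(model$conv)) {
    g <- bw$conv[[l]]
    out[[paste0("W", l)]] <- g$dW
    if (model$use_bias) out[[paste0("b", l)]] <- g$db
    if (!is.null(model$conv[[l]]$bn)) {
      out[[paste0("g", l)]] <- g$dgamma
      out[[paste0("be", l)]] <- g$dbeta
    }
  }
  out$Wd <- bw$dense$dW
  out$bd <- bw$dense$db
  out
}

#' Train a CNN with Adam and categorical cross-entropy
#'
#' Minibatch training with seeded shuffling, best-validation-F1
#' checkpointing and early stopping. The returned model is the checkpoint
#' with the highest validation F1 score.
#'
#' @param spec A `cnn_spec` describing the architecture.
#' @param train_records,val_records Lists of labelled, preprocessed
#'   `ecg_record`s.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param f_last Last-layer feature maps.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience: training stops when the
#'   validation F1 has not improved for this many consecutive epochs.
#' @param seed Seed for initialization and shuffling.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `metrics` (validation
#'   sensitivity/specificity/accuracy/F1 at the checkpoint, in percent),
#'   `history` (per-epoch loss and validation F1) and `epochs_run`.
#' @export
train_model <- function(spec, train_records, val_records, batch_size = 16,
                        learning_rate = 1e-3, f_last = 8, epochs = 30,
                        patience = 5, seed = 1, verbose = FALSE) {
  model <- build_model(spec, f_last = f_last, seed = seed)
  X <- records_to_cube(train_records, model$spec$pad)
  y <- labels_to_index(record_labels(train_records))
  Y <- diag(2)[y, , drop = FALSE]
  Xval <- records_to_cube(val_records, model$spec$pad)
  yval <- record_labels(val_records)
  N <- length(train_records)

  par <- flatten_params(model)
  state <- adam_init(par)
  t_step <- 0
  best <- list(f1 = -Inf, model = model, metrics = NULL, epoch = 0)
  history <- data.frame(epoch = integer(), loss = numeric(), val_f1 = numeric())

  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(N)
      ep_loss <- 0
      n_batch <- 0
      for (start in seq(1, N, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1, N)]
        fw <- cnn_forward(model, X[, , sel, drop = FALSE], train = TRUE,
                          keep = TRUE)
        model <- fw$model                       # running BN statistics
        loss <- cross_entropy(fw$probs, y[sel])
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss in epoch %d)", ep),
               call. = FALSE)
        ep_loss <- ep_loss + loss
        n_batch <- n_batch + 1
        dlogits <- (fw$probs - Y[sel, , drop = FALSE]) / length(sel)
        bw <- cnn_backward(model, fw, dlogits, train = TRUE)
        t_step <- t_step + 1
        upd <- adam_update(flatten_params(model), flatten_grads(model, bw),
                           state, learning_rate, t_step)
        state <- upd$state
        model <- unflatten_params(model, upd$par)
      }
      probs_val <- predict_proba(model, Xval)
      m <- classification_metrics(yval, predict_classes(probs_val))
      history[nrow(history) + 1, ] <- list(ep, ep_loss / n_batch, m$f1)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val F1 %.2f", ep,
                        ep_loss / n_batch, m$f1))
      if (m$f1 > best$f1)
        best <- list(f1 = m$f1, model = model, metrics = m, epoch = ep)
      if (ep - best$epoch >= patience) break
    }
  })
  list(model = best$model, metrics = best$metrics, history = history,
       epochs_run = nrow(history))
}
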