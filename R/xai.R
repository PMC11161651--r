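#' Attribution (xAI) methods
#'
#' Thirteen post-hoc attribution methods produce per-sample relevance maps
#' for a trained CNN and a single record: five gradient-based methods
#' (vanilla gradient, input times gradient, integrated gradients,
#' SmoothGrad, guided backpropagation), five relevance-propagation rules
#' (LRP-Z, LRP-epsilon, LRP-alpha-beta, LRP-w2 and deep Taylor
#' decomposition), two class-activation approaches (GradCAM, GradCAM+) and
#' a Shapley-value gradient estimator with a background dataset.
#'
#' @return `xai_methods()` returns the character vector of the 13 method
#'   names accepted by [explain()].
#' @export
xai_methods <- function() {
  c("gradient", "itg", "ig", "smoothgrad", "guided_bp",
    "lrp_z", "lrp_epsilon", "lrp_alphabeta", "lrp_w2", "dtd",
    "gradcam", "gradcam_plus", "shap")
}

#' Relevance map container
#'
#' @param values Per-sample relevance scores, same length as the unpadded
#'   signal.
#' @param method Method name (see [xai_methods()]).
#' @param target_class Explained class (`"AF"` or `"non-AF"`).
#' @param postprocessing `"abs"` or `"none"`.
#' @return Object of class `relevance_map`.
#' @export
relevance_map <- function(values, method, target_class,
                          postprocessing = "none") {
  if (!all(is.finite(values))) stop("relevance values must be finite", call. = FALSE)
  structure(list(values = values, method = method,
                 target_class = target_class,
                 postprocessing = postprocessing),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map> %s for class %s, %d samples, range [%.3g, %.3g]\n",
              x$method, x$target_class, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

pad_cube <- function(x, pad) array(pad_signal(x, pad), c(1, length(x) + 2 * pad, 1))

crop_pad <- function(v, pad, n) v[(pad + 1):(pad + n)]

target_class_index <- function(model, record, target) {
  if (target %in% ECG_CLASSES) return(match(target, ECG_CLASSES))
  if (target != "predicted") stop("unknown target class", call. = FALSE)
  p <- predict_proba(model, list(record))
  if (p[1, 2] > p[1, 1]) 2L else 1L
}

# d(logit_c)/d(input) on the padded signal; eval-mode batch norm.
input_gradient <- function(model, xp, class_idx, guided = FALSE) {
  fw <- cnn_forward(model, xp, train = FALSE, keep = TRUE)
  dlogits <- matrix(0, 1, 2)
  dlogits[1, class_idx] <- 1
  bw <- cnn_backward(model, fw, dlogits, train = FALSE, guided = guided,
                     param_grads = FALSE)
  list(grad = as.numeric(bw$dX[1, , 1]), fw = fw)
}

#' Compute a relevance map for one record
#'
#' Dispatches to one of the 13 attribution methods. The record's signal is
#' padded with the model's receptive field exactly as during training; the
#' returned map is cropped to the unpadded extent (relevance attributed to
#' the padding is discarded and reported in the `pad_mass` attribute).
#'
#' @param model A trained `ecg_cnn`.
#' @param record A preprocessed `ecg_record`.
#' @param method One of [xai_methods()].
#' @param target `"predicted"` (default) explains the predicted class;
#'   `"AF"` / `"non-AF"` force a class.
#' @param ig_steps Integration steps for integrated gradients.
#' @param sg_noise SmoothGrad noise scale as a fraction of the input range.
#' @param sg_augmentations SmoothGrad heatmap augmentations.
#' @param epsilon Stabilizer for LRP-epsilon (and the alpha-beta
#'   denominators).
#' @param alpha,beta LRP-alpha-beta coefficients (`alpha - beta == 1`).
#' @param cam_layer Convolutional layer explained by GradCAM (default:
#'   last).
#' @param background Background records (list of `ecg_record`s or a numeric
#'   matrix, one column per signal) for the Shapley gradient estimator.
#' @param shap_samples Gradient draws for the Shapley estimator.
#' @param seed Seed for the stochastic methods (SmoothGrad, Shapley).
#' @return A [relevance_map()].
#' @export
explain <- function(model, record, method, target = "predicted",
                    ig_steps = 32, sg_noise = 0.1, sg_augmentations = 32,
                    epsilon = 0.1, alpha = 2, beta = 1,
                    cam_layer = NULL, background = NULL, shap_samples = 64,
                    seed = 1) {
  stopifnot(inherits(model, "ecg_cnn"), inherits(record, "ecg_record"))
  if (!method %in% xai_methods())
    stop(sprintf("unknown attribution method '%s'", method), call. = FALSE)
  x <- record$samples
  n <- length(x)
  pad <- model$spec$pad
  xp <- pad_cube(x, pad)
  cls <- target_class_index(model, record, target)
  post <- "none"

  values <- switch(method,
    gradient = {
      post <- "abs"
      abs(crop_pad(input_gradient(model, xp, cls)$grad, pad, n))
    },
    itg = x * crop_pad(input_gradient(model, xp, cls)$grad, pad, n),
    ig = {
      post <- "abs"
      g <- numeric(n + 2 * pad)
      for (i in seq_len(ig_steps))
        g <- g + input_gradient(model, xp * (i / ig_steps), cls)$grad
      abs(crop_pad(as.numeric(xp[1, , 1]) * g / ig_steps, pad, n))
    },
    smoothgrad = {
      post <- "abs"
      sigma <- sg_noise * diff(range(x))
      g <- with_seed(seed, {
        acc <- numeric(n + 2 * pad)
        for (i in seq_len(sg_augmentations)) {
          noisy <- pad_cube(x + stats::rnorm(n, 0, sigma), pad)
          acc <- acc + input_gradient(model, noisy, cls)$grad
        }
        acc / sg_augmentations
      })
      abs(crop_pad(g, pad, n))
    },
    guided_bp = crop_pad(input_gradient(model, xp, cls, guided = TRUE)$grad,
                         pad, n),
    gradcam = gradcam_values(model, xp, cls, cam_layer, plus = FALSE, n, pad),
    gradcam_plus = gradcam_values(model, xp, cls, cam_layer, plus = TRUE, n, pad),
    lrp_z = propagate_relevance(model, xp, cls, "z", epsilon, alpha, beta),
    lrp_epsilon = propagate_relevance(model, xp, cls, "eps", epsilon, alpha, beta),
    lrp_alphabeta = propagate_relevance(model, xp, cls, "ab", epsilon, alpha, beta),
    lrp_w2 = propagate_relevance(model, xp, cls, "w2", epsilon, alpha, beta),
    dtd = propagate_relevance(model, xp, cls, "dtd", epsilon, alpha, beta),
    shap = shap_values(model, record, cls, background, shap_samples, seed)
  )
  if (method %in% c("lrp_z", "lrp_epsilon", "lrp_alphabeta", "lrp_w2", "dtd")) {
    full <- values
    pad_mass <- sum(full) - sum(crop_pad(full, pad, n))
    values <- crop_pad(full, pad, n)
    out <- relevance_map(values, method, ECG_CLASSES[cls], post)
    attr(out, "pad_mass") <- pad_mass
    return(out)
  }
  relevance_map(values, method, ECG_CLASSES[cls], post)
}

# ---- relevance propagation (LRP rules and deep Taylor decomposition) ----

stab_sign <- function(z, e) z + e * (sign(z) + (z == 0))

# Batch norm (evaluation statistics) folded into the convolution weights,
# so propagation sees a plain conv -> ReLU stack.
fold_bn <- function(model) {
  lapply(model$conv, function(cv) {
    W <- cv$W
    b <- if (model$use_bias) cv$b else numeric(cv$cout)
    if (!is.null(cv$bn)) {
      scale <- cv$bn$gamma / sqrt(cv$bn$rvar + BN_EPS)
      W <- W * scale
      b <- (b - cv$bn$rmean) * scale + cv$bn$beta
    }
    list(W = W, b = b, k = cv$k, s = cv$s, cin = cv$cin, cout = cv$cout)
  })
}

forward_folded <- function(folded, dense, xp) {
  inputs <- vector("list", length(folded))
  A <- xp
  for (l in seq_along(folded)) {
    f <- folded[[l]]
    inputs[[l]] <- A
    Z <- conv1d_fwd(A, f$W, f$b, f$k, f$s)
    A <- Z * (Z > 0)
  }
  gap <- gap_fwd(A)[, 1]
  logits <- as.numeric(dense$W %*% gap + dense$b)
  list(inputs = inputs, A_last = A, gap = gap, logits = logits,
       probs = as.numeric(softmax_rows(matrix(logits, 1))))
}

linear_relevance <- function(a, w, b, R, rule, eps, alpha, beta) {
  z <- a * w
  tiny <- 1e-9
  switch(rule,
    z = z * (R / stab_sign(sum(z) + b, tiny)),
    eps = z * (R / stab_sign(sum(z) + b, eps)),
    ab = {
      zp <- pmax(z, 0); zn <- pmin(z, 0)
      dp <- sum(zp) + max(b, 0)
      dn <- sum(zn) + min(b, 0)
      alpha * zp * (R / stab_sign(dp, eps)) -
        beta * zn * (R / stab_sign(dn, eps))
    },
    w2 = w^2 * (R / stab_sign(sum(w^2), tiny)),
    dtd = {
      zp <- a * pmax(w, 0)
      zp * (R / (sum(zp) + tiny))
    })
}

# Relevance through a conv layer by the named rule, via the convolution
# primitives (transposed convolution implements the backward redistribution).
lrp_conv <- function(rule, X, W, b, k, s, Rout, eps, alpha, beta,
                     input_bounds = NULL) {
  tiny <- 1e-9
  cin <- dim(X)[1]; L <- dim(X)[2]
  Wp <- pmax(W, 0); Wn <- pmin(W, 0)
  zero <- numeric(nrow(W))
  if (rule %in% c("z", "eps")) {
    Z <- conv1d_fwd(X, W, b, k, s)
    S <- Rout / stab_sign(Z, if (rule == "z") tiny else eps)
    X * conv1d_bwd_input(S, W, cin, L, k, s)
  } else if (rule == "ab") {
    bp <- pmax(b, 0); bn <- pmin(b, 0)
    Zp <- conv1d_fwd(X, Wp, bp, k, s)
    Zn <- conv1d_fwd(X, Wn, bn, k, s)
    Sp <- Rout / stab_sign(Zp, eps)
    Sn <- Rout / stab_sign(Zn, eps)
    X * (alpha * conv1d_bwd_input(Sp, Wp, cin, L, k, s) -
         beta * conv1d_bwd_input(Sn, Wn, cin, L, k, s))
  } else if (rule == "w2") {
    W2 <- W^2
    Zw <- conv1d_fwd(array(1, dim(X)), W2, zero, k, s)
    conv1d_bwd_input(Rout / stab_sign(Zw, tiny), W2, cin, L, k, s)
  } else if (rule == "zplus") {
    Zp <- conv1d_fwd(X, Wp, zero, k, s)
    conv_in <- conv1d_bwd_input(Rout / (Zp + tiny), Wp, cin, L, k, s)
    X * conv_in
  } else if (rule == "zB") {
    lo <- input_bounds[1]; hi <- input_bounds[2]
    Z <- conv1d_fwd(X, W, zero, k, s)
    Lc <- array(lo, dim(X)); Hc <- array(hi, dim(X))
    denom <- Z - conv1d_fwd(Lc, Wp, zero, k, s) - conv1d_fwd(Hc, Wn, zero, k, s)
    S <- Rout / stab_sign(denom, tiny)
    X * conv1d_bwd_input(S, W, cin, L, k, s) -
      Lc * conv1d_bwd_input(S, Wp, cin, L, k, s) -
      Hc * conv1d_bwd_input(S, Wn, cin, L, k, s)
  } else stop("unknown propagation rule")
}

# Full backward relevance propagation from the target logit to the input.
# rule: "z", "eps", "ab", "w2" (LRP family, started from the logit) or
# "dtd" (deep Taylor: z+ internally, box rule zB at the [0,1] input,
# started from the softmax probability so the propagated quantity is
# non-negative).
propagate_relevance <- function(model, xp, cls, rule, eps, alpha, beta) {
  if (rule == "ab" && abs(alpha - beta - 1) > 1e-12)
    stop("alpha - beta must equal 1", call. = FALSE)
  if (rule == "dtd") {
    rng <- range(xp)
    if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
      stop("deep Taylor decomposition expects inputs in [0, 1] (preprocessed signals)",
           call. = FALSE)
  }
  folded <- fold_bn(model)
  fw <- forward_folded(folded, model$dense, xp)
  R_start <- if (rule == "dtd") fw$probs[cls] else fw$logits[cls]
  dense_rule <- if (rule == "dtd") "dtd" else rule

  # dense layer
  R_gap <- linear_relevance(fw$gap, model$dense$W[cls, ], model$dense$b[cls],
                            R_start, dense_rule, eps, alpha, beta)
  # GAP: redistribute each channel's relevance over positions proportional
  # to the (non-negative) activations; w2 distributes uniformly.
  A <- fw$A_last
  Lout <- dim(A)[2]
  Rc <- array(0, dim(A))
  for (ch in seq_len(dim(A)[1])) {
    if (rule == "w2") {
      Rc[ch, , 1] <- R_gap[ch] / Lout
    } else {
      tot <- sum(A[ch, , 1])
      if (tot > 0) Rc[ch, , 1] <- A[ch, , 1] / tot * R_gap[ch]
    }
  }
  # conv stack
  for (l in rev(seq_along(folded))) {
    f <- folded[[l]]
    layer_rule <- if (rule == "dtd") (if (l == 1) "zB" else "zplus") else rule
    Rc <- lrp_conv(layer_rule, fw$inputs[[l]], f$W, f$b, f$k, f$s, Rc,
                   eps, alpha, beta, input_bounds = c(0, 1))
  }
  as.numeric(Rc[1, , 1])
}

# ---- GradCAM ----

gradcam_values <- function(model, xp, cls, cam_layer, plus, n, pad) {
  L <- length(model$conv)
  layer <- if (is.null(cam_layer)) L else cam_layer
  if (layer < 1 || layer > L) stop("cam_layer not found", call. = FALSE)
  fw <- cnn_forward(model, xp, train = FALSE, keep = TRUE)
  A <- fw$acts[[layer]]$a                  # C x Lout x 1
  # gradient of the class logit w.r.t. the chosen layer's activations
  dG <- model$dense$W[cls, ]
  dA <- gap_bwd(matrix(dG, ncol = 1), fw$lout)
  if (layer < L) {
    for (l in L:(layer + 1)) {
      cv <- model$conv[[l]]
      ac <- fw$acts[[l]]
      if (!is.null(cv$bn)) {
        sd_ <- sqrt(cv$bn$rvar + BN_EPS)
        br <- bn_relu_bwd(dA, ac$a, ac$xhat, cv$bn$gamma, sd_, FALSE, FALSE)
        dz <- br$dz
      } else {
        dz <- dA * (ac$a > 0)
      }
      dA <- conv1d_bwd_input(dz, cv$W, cv$cin, dim(ac$x_in)[2], cv$k, cv$s)
    }
  }
  g <- dA[, , 1, drop = TRUE]
  if (is.null(dim(g))) g <- matrix(g, nrow = dim(A)[1])
  w_k <- if (plus) rowMeans(pmax(g, 0)) else rowMeans(g)
  map_low <- pmax(colSums(w_k * A[, , 1, drop = TRUE]), 0)
  # project layer positions onto input-sample coordinates
  strides <- model$spec$layers$stride[seq_len(layer)]
  kernels <- model$spec$layers$kernel[seq_len(layer)]
  jump <- prod(utils::head(c(1, strides), layer))
  r_layer <- receptive_field(kernels, strides)
  centers <- (seq_along(map_low) - 1) * jump + (r_layer + 1) / 2 - pad
  stats::approx(centers, map_low, xout = seq_len(n), rule = 2)$y
}

# ---- Shapley values ----

#' Exact Shapley values of a cooperative game
#'
#' Enumerates all coalitions of the `m` players and averages the weighted
#' marginal contributions of each player.
#'
#' @param v Value function: takes an integer vector of player indices
#'   (possibly empty) and returns a scalar.
#' @param m Number of players (enumeration is exponential; limited to 20).
#' @return Numeric vector of the `m` Shapley values.
#' @export
shapley_exact <- function(v, m) {
  if (m > 20) stop("exact enumeration limited to 20 players", call. = FALSE)
  phi <- numeric(m)
  subsets <- 0:(2^m - 1)
  vals <- vapply(subsets, function(mask) v(which(bitwAnd(mask, 2^(0:(m - 1))) > 0)),
                 numeric(1))
  for (i in seq_len(m)) {
    bit <- 2^(i - 1)
    for (mask in subsets) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sum(bitwAnd(mask, 2^(0:(m - 1))) > 0)
      wgt <- 1 / (m * choose(m - 1, s))
      phi[i] <- phi[i] + wgt * (vals[bitwOr(mask, bit) + 1] - vals[mask + 1])
    }
  }
  phi
}

#' Permutation-sampling approximation of Shapley values
#'
#' @inheritParams shapley_exact
#' @param n_draws Number of sampled permutations.
#' @param seed Integer seed.
#' @return Numeric vector of the `m` estimated Shapley values.
#' @export
shapley_sample <- function(v, m, n_draws = 1000, seed = 1) {
  with_seed(seed, {
    phi <- numeric(m)
    for (d in seq_len(n_draws)) {
      perm <- sample(m)
      prev <- v(integer(0))
      for (j in seq_len(m)) {
        cur <- v(sort(perm[seq_len(j)]))
        phi[perm[j]] <- phi[perm[j]] + (cur - prev)
        prev <- cur
      }
    }
    phi / n_draws
  })
}

# Shapley gradient estimator (expected gradients): attributions are the
# average of (x - b) * grad f(b + alpha (x - b)) over background references
# b (cycled deterministically) and alpha ~ U(0, 1).
shap_values <- function(model, record, cls, background, n_samples, seed) {
  if (is.null(background) || (is.list(background) && length(background) == 0))
    stop("a non-empty background dataset is required for shap", call. = FALSE)
  bg <- if (is.list(background))
    vapply(background, function(r) r$samples, numeric(length(record$samples)))
  else as.matrix(background)
  x <- record$samples
  n <- length(x)
  pad <- model$spec$pad
  with_seed(seed, {
    ord <- sample(rep_len(seq_len(ncol(bg)), n_samples))
    acc <- numeric(n)
    for (j in seq_len(n_samples)) {
      b <- bg[, ord[j]]
      a <- stats::runif(1)
      z <- b + a * (x - b)
      g <- crop_pad(input_gradient(model, pad_cube(z, pad), cls)$grad, pad, n)
      acc <- acc + (x - b) * g
    }
    acc / n_samples
  })
}
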