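#' Rank samples by decreasing relevance
#'
#' Ties are broken by ascending sample index, making the ordering
#' deterministic.
#'
#' @param relevance A [relevance_map()] or numeric vector.
#' @return Integer permutation of `1..n` (most relevant first).
#' @export
rank_samples <- function(relevance) {
  v <- if (inherits(relevance, "relevance_map")) relevance$values else relevance
  if (anyNA(v) || any(is.nan(v))) stop("relevance contains NaN", call. = FALSE)
  order(-v, seq_along(v))
}

#' Perturb masked samples by linear interpolation
#'
#' Removes the masked sample values and fills them by linear interpolation
#' between the nearest unmasked neighbours; masked runs touching a signal
#' boundary are extended from the nearest unmasked value. This perturbation
#' preserves the low-frequency structure of the signal and destroys
#' high-frequency information without injecting out-of-distribution jumps.
#'
#' @param x Numeric signal.
#' @param masked Integer indices to perturb (subset of `1..n`).
#' @return Perturbed signal; unmasked samples are unchanged.
#' @export
perturb_interpolation <- function(x, masked) {
  n <- length(x)
  if (length(masked) == 0) return(x)
  keep <- setdiff(seq_len(n), masked)
  if (length(keep) == 0)
    stop("cannot interpolate with every sample masked", call. = FALSE)
  if (length(keep) == 1) {
    out <- rep(x[keep], n)
    out[keep] <- x[keep]
    return(out)
  }
  out <- stats::approx(keep, x[keep], xout = seq_len(n), rule = 2)$y
  out[keep] <- x[keep]
  out
}

#' Perturb masked samples by setting them to zero
#'
#' The prevalent pixel-flipping scheme; on \[0, 1\]-scaled signals it
#' injects jumps unseen during training.
#'
#' @inheritParams perturb_interpolation
#' @return Perturbed signal.
#' @export
perturb_zero <- function(x, masked) {
  x[masked] <- 0
  x
}

#' Pixel-flipping loss curve
#'
#' Progressively perturbs each record's most relevant samples (per the
#' given ranking source), reclassifies, and traces the mean categorical
#' cross-entropy against the true labels as a function of the perturbed
#' fraction.
#'
#' @param model A trained `ecg_cnn`.
#' @param records List of labelled, preprocessed `ecg_record`s.
#' @param rankings List of [relevance_map()]s (or integer orderings), one
#'   per record, or the string `"random"` for seeded random orderings.
#' @param scheme `"interpolation"` or `"zero"`.
#' @param step Fraction-grid step (the grid is `seq(0, 1, by = step)`).
#' @param seed Seed for random orderings.
#' @param chunk Records per forward chunk.
#' @param detail If `TRUE`, the per-record loss matrix
#'   (fractions x records) is attached as element `loss_by_record`.
#' @return Object of class `perturbation_curve`: list with `fractions`,
#'   `loss` (mean over records), `scheme`, `source` and optionally
#'   `loss_by_record`.
#' @export
pixel_flipping <- function(model, records, rankings = "random",
                           scheme = c("interpolation", "zero"), step = 0.02,
                           seed = 1, chunk = 64, detail = FALSE) {
  scheme <- match.arg(scheme)
  n <- length(records[[1]]$samples)
  y <- labels_to_index(record_labels(records))
  random_mode <- identical(rankings, "random")
  src <- if (random_mode) "random"
         else if (inherits(rankings[[1]], "relevance_map"))
           rankings[[1]]$method else "ranking"
  if (random_mode) {
    rankings <- with_seed(seed, lapply(seq_along(records), function(i) sample(n)))
  } else {
    stopifnot(length(rankings) == length(records))
    rankings <- lapply(rankings, function(r)
      if (inherits(r, "relevance_map")) rank_samples(r) else as.integer(r))
    if (any(vapply(rankings, length, integer(1)) != n))
      stop("ranking length does not match record length", call. = FALSE)
  }
  fractions <- seq(0, 1, by = step)
  perturb <- if (scheme == "interpolation") perturb_interpolation else perturb_zero
  loss_mat <- vapply(fractions, function(f) {
    n_mask <- min(ceiling(f * n), if (scheme == "interpolation") n - 1L else n)
    sigs <- vapply(seq_along(records), function(i) {
      xi <- records[[i]]$samples
      if (n_mask == 0) xi else perturb(xi, rankings[[i]][seq_len(n_mask)])
    }, numeric(n))
    X <- array(apply(sigs, 2, pad_signal, r = model$spec$pad),
               c(1, n + 2 * model$spec$pad, length(records)))
    probs <- predict_proba(model, X, chunk = chunk)
    -log(pmax(probs[cbind(seq_along(y), y)], 1e-12))
  }, numeric(length(records)))
  loss_mat <- matrix(loss_mat, ncol = length(fractions))
  out <- list(fractions = fractions, loss = colMeans(loss_mat),
              scheme = scheme, source = src)
  if (detail) out$loss_by_record <- t(loss_mat)
  structure(out, class = "perturbation_curve")
}

#' Relative area under a perturbation curve
#'
#' Trapezoidal area under loss-versus-fraction, normalized by the area
#' spanned by the maximum loss score over the full fraction range.
#'
#' @param curve A `perturbation_curve`.
#' @param normalizer Maximum loss score defining the normalizing area;
#'   must be positive and at least the curve's maximum.
#' @return List with `value` (in \[0, 1\]) and `normalizer`.
#' @export
relative_auc <- function(curve, normalizer = max(curve$loss)) {
  f <- curve$fractions
  l <- curve$loss
  if (normalizer <= 0 || normalizer < max(l) - 1e-12)
    stop("normalizer must be positive and >= the curve maximum", call. = FALSE)
  area <- sum(diff(f) * (utils::head(l, -1) + utils::tail(l, -1)) / 2)
  list(value = area / (normalizer * (max(f) - min(f))), normalizer = normalizer)
}

#' Compare attribution methods by pixel-flipping AUC
#'
#' Runs pixel-flipping for every requested method (plus the random
#' baseline) under the requested schemes and models, and reports the
#' relative AUC per (model, scheme, method). Within one (model, scheme)
#' pair all curves share one normalizer (the maximum loss observed across
#' methods and the random baseline), so the values in a row are mutually
#' comparable.
#'
#' @param models Named list of trained `ecg_cnn`s (e.g.
#'   `list(short = , long = )`).
#' @param records Labelled, preprocessed `ecg_record`s.
#' @param methods Character vector of method names (see [xai_methods()]).
#' @param schemes Perturbation schemes to evaluate.
#' @param step Fraction-grid step.
#' @param seed Seed (random baseline, stochastic methods).
#' @param ... Passed on to [explain()] (e.g. `background`).
#' @return Data frame with columns `model`, `scheme`, `method`, `auc`,
#'   `rank` (1 = best within its model/scheme row).
#' @export
compare_methods <- function(models, records, methods = xai_methods(),
                            schemes = c("interpolation", "zero"),
                            step = 0.02, seed = 1, ...) {
  stopifnot(is.list(models), !is.null(names(models)))
  out <- list()
  for (mtag in names(models)) {
    model <- models[[mtag]]
    maps_by_method <- lapply(methods, function(me)
      lapply(records, function(r) explain(model, r, me, seed = seed, ...)))
    names(maps_by_method) <- methods
    for (sch in schemes) {
      curves <- lapply(methods, function(me)
        pixel_flipping(model, records, maps_by_method[[me]], scheme = sch,
                       step = step, seed = seed))
      names(curves) <- methods
      curves[["random"]] <- pixel_flipping(model, records, "random",
                                           scheme = sch, step = step,
                                           seed = seed)
      normalizer <- max(vapply(curves, function(cu) max(cu$loss), numeric(1)))
      aucs <- vapply(curves, function(cu)
        relative_auc(cu, normalizer)$value, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        model = mtag, scheme = sch, method = names(curves), auc = aucs,
        rank = rank(-aucs, ties.method = "min"), row.names = NULL)
    }
  }
  do.call(rbind, out)
}
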