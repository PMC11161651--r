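#' Hyperparameter grid
#'
#' Default grid explored by the cross-validated search: batch sizes
#' 4/8/16/32, learning rates 1e-3/1e-4/1e-5 and 8/16/24/32 last-layer
#' feature maps.
#'
#' @param batch_sizes,learning_rates,f_last_options Non-empty numeric
#'   vectors.
#' @return Data frame with one row per combination.
#' @export
hyperparam_grid <- function(batch_sizes = c(4, 8, 16, 32),
                            learning_rates = c(1e-3, 1e-4, 1e-5),
                            f_last_options = c(8, 16, 24, 32)) {
  if (!length(batch_sizes) || !length(learning_rates) || !length(f_last_options))
    stop("grid dimensions must be non-empty", call. = FALSE)
  expand.grid(batch_size = batch_sizes, learning_rate = learning_rates,
              f_last = f_last_options, KEEP.OUT.ATTRS = FALSE)
}

#' Select hyperparameters by fold-mean F1 minus fold standard deviation
#'
#' For every grid combination the mean and the (population) standard
#' deviation of the per-fold F1 scores are computed; the combination
#' maximizing `mean - sd` wins. Subtracting the dispersion eliminates
#' combinations whose fold scores vary widely. Ties are broken by the
#' smaller learning rate, then the smaller batch size.
#'
#' @param fold_f1 Data frame with columns `batch_size`, `learning_rate`,
#'   `f_last`, `fold`, `f1` (one row per combination and fold).
#' @return One-row data frame of the winning combination with its
#'   `score = mean - sd`.
#' @export
select_hyperparameters <- function(fold_f1) {
  if (nrow(fold_f1) == 0) stop("empty grid results", call. = FALSE)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  key <- interaction(fold_f1$batch_size, fold_f1$learning_rate,
                     fold_f1$f_last, drop = TRUE)
  agg <- do.call(rbind, lapply(split(fold_f1, key), function(d)
    data.frame(batch_size = d$batch_size[1], learning_rate = d$learning_rate[1],
               f_last = d$f_last[1], score = mean(d$f1) - pop_sd(d$f1))))
  agg <- agg[order(-agg$score, agg$learning_rate, agg$batch_size), ]
  rownames(agg) <- NULL
  agg[1, ]
}

#' Full-scale reference hyperparameters
#'
#' The winning settings of the cross-validated grid search for the
#' original full-scale atrial-fibrillation application, kept as reference
#' values: short-term model batch size 32, learning rate 0.001, 24
#' last-layer feature maps; long-term model batch size 8, learning rate
#' 0.0001, 32 last-layer feature maps. Desk-scale synthetic runs in this
#' package use smaller defaults; these constants document the full-scale
#' operating point.
#'
#' @return Named list with elements `short` and `long`.
#' @export
reference_hyperparameters <- function() {
  list(short = list(batch_size = 32, learning_rate = 1e-3, f_last = 24),
       long = list(batch_size = 8, learning_rate = 1e-4, f_last = 32))
}

#' Ensemble weights
#'
#' The short-term model's weight is fixed at 1; only the long-term weight
#' is optimized.
#'
#' @param w_long Positive weight for the long-term model.
#' @return Object of class `ensemble_weights`.
#' @export
ensemble_weights <- function(w_long = 1) {
  if (w_long <= 0) stop("w_long must be positive", call. = FALSE)
  structure(list(w_short = 1, w_long = w_long), class = "ensemble_weights")
}

#' Weighted softmax averaging of two model outputs
#'
#' Combines the class-probability outputs of the short- and long-term
#' model as `(w_short * p_short + w_long * p_long) / (w_short + w_long)`
#' and classifies by the larger combined value; exact ties resolve to
#' non-AF.
#'
#' @param p_short,p_long Probability 2-vectors or (n x 2) matrices, columns
#'   ordered (non-AF, AF). Rows must sum to 1 within 1e-4.
#' @param weights An [ensemble_weights()] object.
#' @return List with `probs` (combined probabilities, same shape) and
#'   `class` (character vector of decisions).
#' @export
ensemble_predict <- function(p_short, p_long, weights = ensemble_weights()) {
  as_mat <- function(p) if (is.null(dim(p))) matrix(p, ncol = 2) else p
  ps <- as_mat(p_short); pl <- as_mat(p_long)
  if (any(abs(rowSums(ps) - 1) > 1e-4) || any(abs(rowSums(pl) - 1) > 1e-4))
    stop("inputs must be probability vectors (rows summing to 1)", call. = FALSE)
  comb <- (weights$w_short * ps + weights$w_long * pl) /
    (weights$w_short + weights$w_long)
  cls <- ifelse(comb[, 2] > comb[, 1], ECG_CLASSES[2], ECG_CLASSES[1])
  if (is.null(dim(p_short))) comb <- drop(comb)
  list(probs = comb, class = cls)
}

#' Optimize the long-term model weight over validation folds
#'
#' Per fold, evaluates the ensemble F1 on the fold's validation records
#' over a grid of long-term weights (short-term weight fixed at 1) and
#' takes the F1-maximizing weight; when several weights tie (e.g. for
#' identical models the F1 is constant in the weight) the one closest to
#' the neutral value 1 is chosen, with a remaining tie resolving to the
#' smaller weight. The returned weight is the mean over folds.
#'
#' @param model_pairs List of `list(short = , long = )` trained `ecg_cnn`
#'   pairs, one per fold.
#' @param val_folds List of record lists, one per fold (validation data).
#' @param weight_grid Candidate long-term weights.
#' @return An [ensemble_weights()] with the fold-averaged `w_long`.
#' @export
optimize_ensemble_weight <- function(model_pairs, val_folds,
                                     weight_grid = seq(0.25, 3, by = 0.0025)) {
  stopifnot(length(model_pairs) == length(val_folds))
  per_fold <- vapply(seq_along(model_pairs), function(i) {
    records <- val_folds[[i]]
    truth <- record_labels(records)
    if (length(unique(truth)) < 2) {
      warning(sprintf("fold %d has a single class; skipped", i))
      return(NA_real_)
    }
    ps <- predict_proba(model_pairs[[i]]$short, records)
    pl <- predict_proba(model_pairs[[i]]$long, records)
    f1s <- vapply(weight_grid, function(w) {
      pred <- ensemble_predict(ps, pl, ensemble_weights(w))$class
      classification_metrics(truth, pred)$f1
    }, numeric(1))
    best <- weight_grid[f1s >= max(f1s) - 1e-9]
    best[order(abs(best - 1), best)][1]
  }, numeric(1))
  ensemble_weights(mean(per_fold, na.rm = TRUE))
}

#' Bundle a short- and a long-term model into an ensemble
#'
#' @param short,long Trained `ecg_cnn` models.
#' @param weights An [ensemble_weights()].
#' @return Object of class `ecg_ensemble`.
#' @export
ecg_ensemble <- function(short, long, weights = ensemble_weights()) {
  structure(list(short = short, long = long, weights = weights),
            class = "ecg_ensemble")
}

#' @export
evaluate.ecg_ensemble <- function(object, records) {
  ps <- predict_proba(object$short, records)
  pl <- predict_proba(object$long, records)
  pred <- ensemble_predict(ps, pl, object$weights)$class
  classification_metrics(record_labels(records), pred)
}
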