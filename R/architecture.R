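#' Receptive field of a stack of 1D convolutions
#'
#' For layers `l = 1..L` with kernel sizes `k_l` and strides `s_l`, the
#' receptive field of one neuron in the last layer with respect to the
#' input is
#' \deqn{r = \sum_{l=1}^{L} (k_l - 1) \prod_{i=1}^{l-1} s_i + 1.}
#'
#' @param kernels Integer vector of kernel sizes (all >= 1).
#' @param strides Integer vector of strides, same length (all >= 1).
#' @return The receptive field in input samples.
#' @export
receptive_field <- function(kernels, strides) {
  if (length(kernels) == 0 || length(kernels) != length(strides))
    stop("kernels and strides must be non-empty vectors of equal length",
         call. = FALSE)
  if (any(kernels < 1) || any(strides < 1))
    stop("kernel and stride sizes must be positive", call. = FALSE)
  jumps <- cumprod(c(1, strides[-length(strides)]))
  sum((kernels - 1) * jumps) + 1
}

#' Constraints for the receptive-field solver
#'
#' @param target_r Desired receptive field in samples (must be met exactly).
#' @param n_layers Number of convolutional layers.
#' @param kernel_range Inclusive kernel-size interval searched per layer.
#' @param stride_range Inclusive stride interval searched per layer.
#' @param max_stride_product Cap on the cumulative stride product
#'   (total temporal downsampling). The last convolutional layer's
#'   temporal resolution is `max_stride_product / fs` seconds; the default
#'   of 64 (128 ms at 500 Hz) keeps beat-to-beat timing — the rhythmic
#'   class signal, whose dispersion differs by roughly 100 ms between
#'   regular and fibrillating rhythms — resolvable by the deep layers, and
#'   retains well over a hundred temporal positions for the
#'   global-average-pooling head on a 10-s input. Architectures that
#'   downsample much more aggressively were found to plateau near chance
#'   on purely rhythmic class signals.
#' @param objective `"early_downsampling"` (default) prefers the
#'   lexicographically largest stride vector, concentrating temporal
#'   downsampling in the first layers, which minimizes computation and
#'   parameter count for a given receptive field; `"late_downsampling"`
#'   prefers the lexicographically smallest stride vector (full temporal
#'   resolution retained as long as possible). Given the chosen strides,
#'   kernels are assigned by minimizing the maximum kernel size, ties
#'   broken by the lexicographically smallest vector, making the solver
#'   fully deterministic.
#' @return An object of class `solver_constraints`.
#' @export
solver_constraints <- function(target_r, n_layers = 9,
                               kernel_range = c(2, 24),
                               stride_range = c(1, 4),
                               max_stride_product = 64,
                               objective = c("early_downsampling",
                                             "late_downsampling")) {
  objective <- match.arg(objective)
  if (target_r < 1) stop("target_r must be >= 1", call. = FALSE)
  stopifnot(n_layers >= 1, kernel_range[1] >= 1, stride_range[1] >= 1,
            kernel_range[2] >= kernel_range[1],
            stride_range[2] >= stride_range[1], max_stride_product >= 1)
  structure(list(target_r = target_r, n_layers = n_layers,
                 kernel_range = kernel_range, stride_range = stride_range,
                 max_stride_product = max_stride_product,
                 objective = objective),
            class = "solver_constraints")
}

# Range of receptive fields (minus one) achievable when the cumulative
# stride products ("jumps") of the first q layers are fixed.
rf_bounds <- function(jumps_fixed, L, amin, amax, smin, smax, cap = Inf) {
  q <- length(jumps_fixed)
  jmin <- jmax <- jumps_fixed
  if (q < L) {
    last <- jumps_fixed[q]
    jmin <- c(jmin, last * smin^seq_len(L - q))
    jmax <- c(jmax, pmin(last * smax^seq_len(L - q), cap))
  }
  c(sum(amin * jmin), sum(amax * jmax))
}

# Lexicographically smallest kernel vector with sum((k-1) * jumps) == target,
# k - 1 constrained to [amin, amax]. Interval and gcd pruning keep the
# backtracking search shallow.
solve_kernels <- function(jumps, target, amin, amax) {
  L <- length(jumps)
  sufmin <- c(rev(cumsum(rev(jumps * amin))), 0)
  sufmax <- c(rev(cumsum(rev(jumps * amax))), 0)
  sufgcd <- integer(L + 1)
  sufgcd[L + 1] <- 0L
  g <- function(x, y) ifelse(y == 0, x, Recall(y, x %% y))
  for (l in rev(seq_len(L)))
    sufgcd[l] <- if (l == L) jumps[L] else g(jumps[l], sufgcd[l + 1])
  a <- integer(L)
  rec <- function(l, rem) {
    if (l > L) return(rem == 0)
    if (l <= L && rem %% sufgcd[l] != 0) return(FALSE)
    for (cand in amin:amax) {
      rest <- rem - cand * jumps[l]
      if (rest < sufmin[l + 1] || rest > sufmax[l + 1]) next
      a[l] <<- cand
      if (rec(l + 1, rest)) return(TRUE)
    }
    FALSE
  }
  if (rec(1, target)) a + 1 else NULL
}

# Kernel assignment minimizing the maximum kernel size, ties broken by the
# lexicographically smallest vector: raise the per-layer cap until the
# target is representable.
solve_kernels_balanced <- function(jumps, target, amin, amax) {
  for (cap in amin:amax) {
    sol <- solve_kernels(jumps, target, amin, cap)
    if (!is.null(sol)) return(sol)
  }
  NULL
}

#' Solve the receptive-field equation for a layer configuration
#'
#' Depth-first search over stride vectors (ordered by the objective) with
#' interval pruning; for each stride vector the kernels are back-solved to
#' meet `target_r` exactly. The first solution in the deterministic search
#' order is returned, so identical constraints always yield an identical
#' configuration.
#'
#' @param constraints A [solver_constraints()] object.
#' @param f_last Number of feature maps in the last convolutional layer.
#'   Layers in the first third of the network receive `4 * f_last` maps,
#'   the middle third `2 * f_last`, the final third `f_last`.
#' @return A `cnn_spec`: list with a `layers` data frame (kernel, stride,
#'   feature_maps, batch_norm, activation), the receptive field `r`, the
#'   per-side padding `pad` (equal to `r`), and `f_last`.
#' @export
solve_configuration <- function(constraints, f_last = 8) {
  stopifnot(inherits(constraints, "solver_constraints"))
  L <- constraints$n_layers
  target <- constraints$target_r - 1
  amin <- constraints$kernel_range[1] - 1
  amax <- constraints$kernel_range[2] - 1
  smin <- constraints$stride_range[1]
  smax <- constraints$stride_range[2]
  cap <- constraints$max_stride_product
  stride_order <- if (constraints$objective == "early_downsampling")
    seq(smax, smin) else seq(smin, smax)

  overall <- rf_bounds(1, L, amin, amax, smin, smax, cap)
  if (target < overall[1] || target > overall[2])
    stop(sprintf(paste0("target receptive field %d infeasible: achievable ",
                        "range is [%d, %d]"),
                 constraints$target_r, overall[1] + 1, overall[2] + 1),
         call. = FALSE)

  search <- function(strides) {
    m <- length(strides)
    jumps <- cumprod(c(1, strides))[seq_len(min(m + 1, L))]
    if (m < L) {
      b <- rf_bounds(jumps, L, amin, amax, smin, smax, cap)
      if (target < b[1] || target > b[2]) return(NULL)
      if (m == L - 1) {
        # the last stride does not influence r; keep it minimal, which also
        # maximizes the number of positions entering global average pooling
        k <- solve_kernels_balanced(jumps, target, amin, amax)
        if (is.null(k)) return(NULL)
        return(list(strides = c(strides, smin), kernels = k))
      }
      prod_now <- jumps[length(jumps)]
      for (s in stride_order) {
        if (prod_now * s > cap) next
        res <- search(c(strides, s))
        if (!is.null(res)) return(res)
      }
      return(NULL)
    }
    NULL
  }
  sol <- search(integer(0))
  if (is.null(sol))
    stop(sprintf("no exact configuration found for receptive field %d",
                 constraints$target_r), call. = FALSE)
  cnn_spec(kernels = sol$kernels, strides = sol$strides, f_last = f_last)
}

#' Construct a CNN specification
#'
#' Describes a stack of 1D convolutional layers (each followed by batch
#' normalization and ReLU), a global-average-pooling head and a softmax
#' layer of size two. The per-side edge padding equals the receptive field.
#'
#' @param kernels,strides Integer vectors of equal length.
#' @param f_last Feature maps in the last layer; earlier thirds get 4x/2x.
#' @param batch_norm Logical; include batch normalization in every layer.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(kernels, strides, f_last = 8, batch_norm = TRUE) {
  L <- length(kernels)
  r <- receptive_field(kernels, strides)
  tier <- ceiling(3 * seq_len(L) / L)             # 1..3 thirds of the stack
  maps <- f_last * c(4, 2, 1)[tier]
  structure(list(
    layers = data.frame(kernel = as.integer(kernels),
                        stride = as.integer(strides),
                        feature_maps = as.integer(maps),
                        batch_norm = batch_norm,
                        activation = "relu"),
    r = r, pad = r, f_last = f_last, n_layers = L),
    class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> %d conv layers, receptive field %d samples, pad %d/side\n",
              x$n_layers, x$r, x$pad))
  cat(sprintf("  kernels: %s\n", paste(x$layers$kernel, collapse = " ")))
  cat(sprintf("  strides: %s\n", paste(x$layers$stride, collapse = " ")))
  cat(sprintf("  feature maps: %s\n", paste(x$layers$feature_maps, collapse = " ")))
  invisible(x)
}

#' Edge-replication padding congruent with the receptive field
#'
#' Prepends `r` copies of the first sample and appends `r` copies of the
#' last sample, so that edge samples are covered by as many receptive
#' fields as central samples.
#'
#' @param x Numeric signal (non-empty).
#' @param r Padding length per side (the model's receptive field).
#' @return Padded signal of length `length(x) + 2 * r`.
#' @export
pad_signal <- function(x, r) {
  if (length(x) == 0) stop("cannot pad an empty signal", call. = FALSE)
  if (r < 0) stop("padding must be non-negative", call. = FALSE)
  if (r == 0) return(x)
  c(rep(x[1], r), x, rep(x[length(x)], r))
}

#' Serialize a CNN spec to JSON
#' @param spec A `cnn_spec`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cnn_spec <- function(spec, path) {
  jsonlite::write_json(list(layers = spec$layers, r = spec$r, pad = spec$pad,
                            f_last = spec$f_last),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
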