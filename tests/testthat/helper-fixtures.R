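# Shared fixtures. Heavy objects (datasets, trained model pairs,
# perturbation curves) are memoised so that several test files can reuse
# the same study conditions without retraining.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

condition_config <- function(condition) {
  switch(condition,
         default = ecg_generator_config(),
         rhythm = ecg_generator_config(rhythm_only = TRUE),
         morphology = ecg_generator_config(morphology_only = TRUE),
         stop("unknown condition"))
}

# Preprocessed, class-balanced dataset under one study condition.
desk_dataset <- function(condition = "default", n_per_class = 200, seed = 1) {
  memo(sprintf("ds-%s-%d-%d", condition, n_per_class, seed),
       preprocess_dataset(generate_dataset(condition_config(condition),
                                           n_per_class, seed * 1009)))
}

spec_short <- function() memo("spec300",
  solve_configuration(solver_constraints(300)))
spec_long <- function() memo("spec5000",
  solve_configuration(solver_constraints(5000)))

# Short- and long-term models trained under one condition and seed:
# 100 held-out records for perturbation analysis, four folds for
# training, one fold for validation-based checkpointing.
trained_pair <- function(condition = "default", seed = 1, n_per_class = 200) {
  memo(sprintf("pair-%s-%d-%d", condition, seed, n_per_class), {
    ds <- desk_dataset(condition, n_per_class, seed)
    sp <- train_test_split_records(ds, test_fraction = 0.25, n_folds = 5,
                                   seed = seed)
    train <- do.call(c, sp$folds[1:4])
    val <- sp$folds[[5]]
    short <- train_model(spec_short(), train, val,
                         epochs = 30, patience = 8, seed = seed)
    long <- train_model(spec_long(), train, val,
                        epochs = 30, patience = 8, seed = seed)
    list(short = short, long = long, train = train,
         val = val, test = sp$test)
  })
}

# Random-ranking perturbation curve for a trained model (memoised; the
# noise-floor and faithfulness tests share these).
random_curve <- function(condition, seed, which = c("short", "long"),
                         scheme = "interpolation", step = 0.05) {
  which <- match.arg(which)
  memo(sprintf("curve-%s-%d-%s-%s-%g", condition, seed, which, scheme, step), {
    pair <- trained_pair(condition, seed)
    pixel_flipping(pair[[which]]$model, pair$test, "random", scheme = scheme,
                   step = step, seed = seed, detail = TRUE)
  })
}

# Independent receptive-field oracle: feed a delta at every input position
# through an all-ones convolution stack and measure the span (first to
# last input position) that reaches the first output neuron of the last
# layer. The receptive field is an extent: with stride > kernel the
# windows leave uncovered holes inside the span.
empirical_receptive_field <- function(kernels, strides) {
  r_guess <- 1 + sum((kernels - 1) * cumprod(c(1, strides[-length(strides)])))
  L_in <- r_guess + 16
  forward_ones <- function(x) {
    A <- array(x, c(1, length(x), 1))
    cin <- 1
    for (l in seq_along(kernels)) {
      W <- matrix(1, 1, cin * kernels[l])
      A <- ecgxai:::conv1d_fwd(A, W, 0, kernels[l], strides[l])
      cin <- 1
    }
    A[1, 1, 1]     # first output neuron of the last layer
  }
  base <- forward_ones(rep(0, L_in))
  hits <- vapply(seq_len(L_in), function(i) {
    x <- rep(0, L_in)
    x[i] <- 1
    forward_ones(x) != base
  }, logical(1))
  diff(range(which(hits))) + 1
}

# Tiny linear "model": one full-width convolution (no batch norm, no bias),
# positive dense read-out, zero padding. With positive pre-activations the
# ReLU is inactive and logit 1 equals sum(w * x).
linear_toy_model <- function(w) {
  n <- length(w)
  spec <- cnn_spec(kernels = n, strides = 1, f_last = 1, batch_norm = FALSE)
  m <- build_model(spec, seed = 1, use_bias = FALSE)
  m$conv[[1]]$W <- matrix(w, 1, n)
  m$dense$W <- matrix(c(1, 0), 2, 1)
  m$dense$b <- c(0, 0)
  m$spec$pad <- 0       # keep the map exactly linear (no replicated edges)
  m
}

as_record <- function(x, label = "non-AF") {
  structure(list(samples = x, fs = 500, label = label,
                 r_peaks = integer(0), p_waves = integer(0),
                 rr_intervals = integer(0), record_id = "toy", seed = 0L),
            class = "ecg_record")
}

# Small random CNN for gradient / propagation checks.
toy_cnn <- function(seed = 1, batch_norm = FALSE, use_bias = FALSE,
                    positive_weights = FALSE) {
  spec <- cnn_spec(kernels = c(5, 3, 3), strides = c(2, 2, 1), f_last = 2,
                   batch_norm = batch_norm)
  m <- build_model(spec, seed = seed, use_bias = use_bias)
  if (positive_weights) {
    for (l in seq_along(m$conv)) m$conv[[l]]$W <- abs(m$conv[[l]]$W)
    m$dense$W <- abs(m$dense$W)
  }
  m
}

toy_record <- function(n = 64, seed = 5) {
  set.seed(seed)
  as_record(stats::runif(n))
}
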