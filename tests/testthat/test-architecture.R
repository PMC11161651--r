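test_that("receptive-field formula matches index-tracing on worked cases", {
  expect_equal(receptive_field(rep(3, 9), rep(1, 9)), 19)
  expect_equal(receptive_field(c(3, 3), c(2, 1)), 7)
  expect_equal(empirical_receptive_field(c(3, 3), c(2, 1)), 7)
  expect_equal(receptive_field(c(5, 3, 3), c(1, 2, 2)), 11)
  expect_equal(empirical_receptive_field(c(5, 3, 3), c(1, 2, 2)), 11)
  expect_error(receptive_field(integer(0), integer(0)), "non-empty")
  expect_error(receptive_field(c(3, 0), c(1, 1)), "positive")
  expect_error(receptive_field(c(3, 3), 1), "equal length")
})

test_that("solver meets targets exactly and is deterministic", {
  s300 <- solve_configuration(solver_constraints(300))
  expect_s3_class(s300, "cnn_spec")
  expect_equal(s300$n_layers, 9)
  expect_equal(receptive_field(s300$layers$kernel, s300$layers$stride), 300)
  expect_equal(s300$pad, 300)

  s5000 <- solve_configuration(solver_constraints(5000))
  expect_equal(receptive_field(s5000$layers$kernel, s5000$layers$stride), 5000)

  expect_identical(solve_configuration(solver_constraints(300)), s300)

  # feature-map schedule: thirds at 4x / 2x / 1x of the last layer
  expect_equal(s300$layers$feature_maps, rep(c(32, 16, 8), each = 3))
  s24 <- solve_configuration(solver_constraints(300), f_last = 24)
  expect_equal(s24$layers$feature_maps, rep(c(96, 48, 24), each = 3))
})

test_that("kernel tie-break minimizes the maximum kernel, then lexicographic", {
  # all strides 1, r = 19: the balanced assignment is k = 3 everywhere
  s <- solve_configuration(solver_constraints(19, stride_range = c(1, 1)))
  expect_equal(s$layers$kernel, rep(3, 9))

  # brute-force oracle on a small instance: 3 layers, fixed strides
  strides <- c(2, 2, 1)
  jumps <- cumprod(c(1, strides[-3]))
  target <- 17
  grid <- expand.grid(k1 = 2:7, k2 = 2:7, k3 = 2:7)
  feas <- grid[apply(grid, 1, function(k)
    sum((k - 1) * jumps) + 1 == target), , drop = FALSE]
  kmax <- apply(feas, 1, max)
  cand <- feas[kmax == min(kmax), , drop = FALSE]
  cand <- cand[do.call(order, as.list(cand)), , drop = FALSE]
  oracle <- as.integer(cand[1, ])
  s3 <- solve_configuration(solver_constraints(17, n_layers = 3,
                                               kernel_range = c(2, 7),
                                               stride_range = c(2, 2)))
  # stride DFS picks [2,2,2] (last stride does not affect r; kept minimal)
  expect_equal(s3$layers$stride, c(2, 2, 2))
  expect_equal(s3$layers$kernel, oracle)
})

test_that("infeasible targets raise an informative error", {
  expect_error(solve_configuration(solver_constraints(2)), "achievable")
  expect_error(solve_configuration(solver_constraints(10^7)), "achievable")
})

test_that("padding replicates edge values congruent with the receptive field", {
  expect_equal(pad_signal(c(1, 2, 3), 2), c(1, 1, 1, 2, 3, 3, 3))
  x <- rnorm(10)
  expect_identical(pad_signal(x, 0), x)
  expect_length(pad_signal(rnorm(5000), 300), 5600)
  expect_error(pad_signal(numeric(0), 2), "empty")
  expect_error(pad_signal(1:3, -1), "non-negative")
})

test_that("built models are seeded, probabilistic and length-agnostic", {
  spec <- spec_short()
  m1 <- build_model(spec, seed = 5)
  m2 <- build_model(spec, seed = 5)
  expect_identical(m1$conv[[3]]$W, m2$conv[[3]]$W)
  m3 <- build_model(spec, seed = 6)
  expect_false(identical(m1$conv[[1]]$W, m3$conv[[1]]$W))

  set.seed(2)
  x5000 <- runif(5000)
  p <- predict_proba(m1, list(as_record(x5000)))
  expect_equal(unname(rowSums(p)), 1, tolerance = 1e-6)
  # global average pooling decouples the classifier from the input length
  p2 <- predict_proba(m1, list(as_record(runif(2500))))
  expect_equal(unname(rowSums(p2)), 1, tolerance = 1e-6)
})

test_that("the built network realizes the specified receptive field", {
  # positive weights and positive inputs keep every unit active, so an
  # input perturbation reaches the last layer iff it lies in the field
  m <- toy_cnn(positive_weights = TRUE)
  r <- m$spec$r
  L_in <- r + 12
  base_in <- array(0.5, c(1, L_in, 1))
  fw0 <- ecgxai:::cnn_forward(m, base_in, keep = TRUE)
  a0 <- fw0$acts[[3]]$a[, 1, 1]
  hits <- vapply(seq_len(L_in), function(i) {
    x <- base_in
    x[1, i, 1] <- 1
    fw <- ecgxai:::cnn_forward(m, x, keep = TRUE)
    any(fw$acts[[3]]$a[, 1, 1] != a0)
  }, logical(1))
  expect_equal(diff(range(which(hits))) + 1, r)
})
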