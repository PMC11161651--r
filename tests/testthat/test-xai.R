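test_that("the method registry exposes exactly the 13 methods", {
  expect_length(xai_methods(), 13)
  expect_setequal(xai_methods(),
                  c("gradient", "itg", "ig", "smoothgrad", "guided_bp",
                    "lrp_z", "lrp_epsilon", "lrp_alphabeta", "lrp_w2", "dtd",
                    "gradcam", "gradcam_plus", "shap"))
  m <- linear_toy_model(c(1, 1))
  expect_error(explain(m, as_record(c(0.5, 0.5)), "saliency"), "unknown")
})

test_that("gradient-family methods are exact on a linear map", {
  w <- c(3, -1, 2, 0.5)
  m <- linear_toy_model(w)
  x <- c(1, 2, 0.5, 1.5)        # w.x = 4 > 0: ReLU inactive
  rec <- as_record(x)

  g <- explain(m, rec, "gradient", target = "non-AF")
  expect_equal(g$values, abs(w))
  expect_equal(g$postprocessing, "abs")

  itg <- explain(m, rec, "itg", target = "non-AF")
  expect_equal(itg$values, x * w)

  # IG with zero baseline: completeness is exact for a linear function
  ig <- explain(m, rec, "ig", target = "non-AF")
  expect_equal(ig$values, abs(x * w), tolerance = 1e-10)
  expect_equal(sum(x * w), 2.75)
})

test_that("LRP-Z implements the z-rule and conserves relevance", {
  m <- linear_toy_model(c(3, -1))
  rec <- as_record(c(1, 2))     # f = 3*1 - 1*2 = 1
  r <- explain(m, rec, "lrp_z", target = "non-AF")
  expect_equal(r$values, c(3, -2), tolerance = 1e-6)
  expect_equal(sum(r$values), 1, tolerance = 1e-6)
})

test_that("LRP-epsilon shrinks relevance monotonically in epsilon", {
  m <- linear_toy_model(c(3, -1, 2))
  rec <- as_record(c(1, 2, 1))
  maps <- lapply(c(0.1, 1, 10), function(e)
    explain(m, rec, "lrp_epsilon", target = "non-AF", epsilon = e)$values)
  expect_true(all(abs(maps[[2]]) < abs(maps[[1]])))
  expect_true(all(abs(maps[[3]]) < abs(maps[[2]])))
  expect_true(all(sign(maps[[1]]) == sign(maps[[2]])))
  expect_true(all(sign(maps[[2]]) == sign(maps[[3]])))
})

test_that("propagation rules match closed forms on single layers", {
  # w2 rule ignores the input entirely
  W <- matrix(c(1, -2, 3, 0.5), 1, 4)
  X0 <- array(0, c(1, 4, 1))
  Rout <- array(5, c(1, 1, 1))
  r_w2 <- ecgxai:::lrp_conv("w2", X0, W, 0, 4, 1, Rout, 0.1, 2, 1)
  expect_equal(as.numeric(r_w2[1, , 1]), as.numeric(W^2 / sum(W^2) * 5),
               tolerance = 1e-6)

  # zB rule on zero input draws relevance from the box bounds and conserves
  r_zb <- ecgxai:::lrp_conv("zB", X0, W, 0, 4, 1, Rout, 0.1, 2, 1,
                            input_bounds = c(0, 1))
  expect_equal(sum(r_zb), 5, tolerance = 1e-4)

  # alpha - beta must differ by one
  m <- toy_cnn()
  expect_error(explain(m, toy_record(), "lrp_alphabeta", alpha = 2, beta = 0.5),
               "alpha - beta")
})

test_that("deep Taylor maps are non-negative and reduce to LRP-Z on positive nets", {
  m <- toy_cnn(seed = 4, positive_weights = TRUE)
  rec <- toy_record(seed = 6)
  d <- explain(m, rec, "dtd")
  expect_gte(min(d$values), 0)

  z <- explain(m, rec, "lrp_z", target = d$target_class)
  # same distribution up to the different starting relevance
  expect_gt(sum(d$values), 0)
  expect_equal(d$values / sum(d$values), z$values / sum(z$values),
               tolerance = 1e-6)

  # out-of-box inputs are rejected
  expect_error(explain(m, as_record(runif(64) * 3), "dtd"), "\\[0, 1\\]")
})

test_that("non-negativity holds for the declared methods on a generic net", {
  m <- toy_cnn(seed = 8, batch_norm = TRUE, use_bias = TRUE)
  rec <- toy_record(seed = 9)
  for (me in c("gradient", "ig", "smoothgrad", "dtd", "gradcam", "gradcam_plus"))
    expect_gte(min(explain(m, rec, me)$values), 0)
})

test_that("GradCAM zeroes fully negative contributions; GradCAM+ clips weights", {
  # force negative class-1 dense weights: every channel's gradient < 0
  m <- toy_cnn(seed = 10, positive_weights = TRUE)
  m$dense$W <- -abs(m$dense$W)
  rec <- toy_record(seed = 11)
  cam <- explain(m, rec, "gradcam", target = "non-AF")
  camp <- explain(m, rec, "gradcam_plus", target = "non-AF")
  expect_true(all(cam$values == 0))
  expect_true(all(camp$values == 0))

  expect_error(explain(m, rec, "gradcam", cam_layer = 99), "cam_layer")
})

test_that("Shapley values: exact enumeration, sampling and the gradient estimator", {
  v <- function(S) {
    if (length(S) == 0) return(0)
    if (identical(S, 1L) || identical(S, 1)) return(1)
    if (identical(S, 2L) || identical(S, 2)) return(2)
    4
  }
  exact <- shapley_exact(v, 2)
  expect_equal(exact, c(1.5, 2.5))
  est <- shapley_sample(v, 2, n_draws = 10000, seed = 1)
  expect_lt(max(abs(est - exact)), 0.1)
  expect_identical(shapley_sample(v, 2, 100, seed = 3),
                   shapley_sample(v, 2, 100, seed = 3))

  # gradient estimator on a linear model with zero background = x * w
  w <- c(2, -1, 0.5, 1)
  m <- linear_toy_model(w)
  x <- c(0.5, 1, 2, 1)
  bg <- matrix(0, 4, 1)
  sh <- explain(m, as_record(x), "shap", target = "non-AF", background = bg,
                shap_samples = 16)
  expect_equal(sh$values, x * w, tolerance = 1e-10)

  # efficiency: contributions sum to f(x) - mean f(background)
  bg2 <- matrix(runif(8, 0, 0.2), 4, 2)
  sh2 <- explain(m, as_record(x), "shap", target = "non-AF", background = bg2,
                 shap_samples = 64)
  f <- function(z) sum(z * w)
  expect_equal(sum(sh2$values), f(x) - mean(apply(bg2, 2, f)),
               tolerance = 0.02 * abs(f(x)))

  expect_error(explain(m, as_record(x), "shap", background = list()),
               "background")
})

test_that("stochastic explanation methods are reproducible from their seed", {
  m <- toy_cnn(seed = 12, batch_norm = TRUE, use_bias = TRUE)
  rec <- toy_record(seed = 13)
  a <- explain(m, rec, "smoothgrad", seed = 7)
  b <- explain(m, rec, "smoothgrad", seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(explain(m, rec, "smoothgrad", seed = 8)$values,
                         a$values))
  bg <- matrix(runif(64 * 3), 64, 3)
  s1 <- explain(m, rec, "shap", background = bg, seed = 7)
  s2 <- explain(m, rec, "shap", background = bg, seed = 7)
  expect_identical(s1$values, s2$values)
})

test_that("guided backpropagation suppresses negative upstream gradients", {
  m <- toy_cnn(seed = 14, batch_norm = TRUE, use_bias = TRUE)
  rec <- toy_record(seed = 15)
  gb <- explain(m, rec, "guided_bp")
  expect_length(gb$values, length(rec$samples))
  expect_true(all(is.finite(gb$values)))
  # guided maps differ from the raw gradient when negatives are clipped
  g <- explain(m, rec, "gradient")
  expect_false(isTRUE(all.equal(abs(gb$values), g$values)))
})
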