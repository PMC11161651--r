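test_that("confusion-matrix metrics match hand computation", {
  truth <- c(rep("AF", 50), rep("non-AF", 50))
  pred <- c(rep("AF", 48), rep("non-AF", 2), rep("AF", 5), rep("non-AF", 45))
  m <- classification_metrics(truth, pred)
  expect_equal(m$sensitivity, 96)
  expect_equal(m$specificity, 90)
  expect_equal(m$accuracy, 93)
  expect_equal(m$f1, 100 * 96 / 103, tolerance = 1e-10)

  perfect <- classification_metrics(truth, truth)
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100, f1 = 100))
  allpos <- classification_metrics(truth, rep("AF", 100))
  expect_equal(allpos$sensitivity, 100)
  expect_equal(allpos$specificity, 0)
  expect_error(classification_metrics(character(0), character(0)), "no records")
})

test_that("hyperparameter selection maximizes fold mean minus population sd", {
  tab <- data.frame(
    batch_size = rep(c(16, 32), each = 5), learning_rate = 1e-3, f_last = 8,
    fold = rep(1:5, 2),
    f1 = c(rep(0.9, 5), c(1, 1, 1, 0.6, 0.6)))
  win <- select_hyperparameters(tab)
  expect_equal(win$batch_size, 16)        # 0.900 beats 0.84 - 0.196 = 0.644
  expect_equal(win$score, 0.9)

  # permutation invariance in fold order
  win2 <- select_hyperparameters(tab[sample(nrow(tab)), ])
  expect_equal(win2$batch_size, win$batch_size)

  single <- select_hyperparameters(data.frame(batch_size = 4,
                                              learning_rate = 1e-4,
                                              f_last = 8, fold = 1:2,
                                              f1 = c(0.5, 0.7)))
  expect_equal(single$batch_size, 4)
  expect_error(select_hyperparameters(tab[0, ]), "empty")

  # ties resolve to the smaller learning rate, then smaller batch
  tie <- data.frame(batch_size = c(8, 4), learning_rate = c(1e-3, 1e-4),
                    f_last = 8, fold = 1, f1 = c(0.8, 0.8))
  expect_equal(select_hyperparameters(tie)$learning_rate, 1e-4)
})

test_that("the full-scale reference settings are recorded", {
  ref <- reference_hyperparameters()
  expect_equal(ref$short, list(batch_size = 32, learning_rate = 1e-3,
                               f_last = 24))
  expect_equal(ref$long, list(batch_size = 8, learning_rate = 1e-4,
                              f_last = 32))
  g <- hyperparam_grid()
  expect_equal(nrow(g), 4 * 3 * 4)
  expect_error(hyperparam_grid(batch_sizes = numeric(0)), "non-empty")
})

test_that("weighted softmax averaging combines and classifies correctly", {
  res <- ensemble_predict(c(0.6, 0.4), c(0.3, 0.7),
                          ensemble_weights(w_long = 1.2675))
  expect_equal(res$probs, c(0.4323, 0.5677), tolerance = 5e-5)
  expect_equal(res$class, "AF")
  expect_equal(sum(res$probs), 1, tolerance = 1e-12)

  same <- ensemble_predict(c(0.6, 0.4), c(0.6, 0.4), ensemble_weights(1))
  expect_equal(same$probs, c(0.6, 0.4))

  # dominant long weight follows the long model's decision
  dom <- ensemble_predict(c(0.9, 0.1), c(0.1, 0.9), ensemble_weights(1e6))
  expect_equal(dom$class, "AF")

  tie <- ensemble_predict(c(0.5, 0.5), c(0.5, 0.5), ensemble_weights(1))
  expect_equal(tie$class, "non-AF")

  expect_error(ensemble_predict(c(0.7, 0.4), c(0.5, 0.5), ensemble_weights(1)),
               "probability")
  expect_error(ensemble_weights(0), "positive")
})

test_that("training separates the synthetic classes and is seed-stable", {
  pair <- trained_pair("default", seed = 1)
  expect_gte(pair$short$metrics$f1, 95)
  expect_gte(pair$long$metrics$f1, 95)
  expect_lte(pair$short$epochs_run, 30)

  # seeded determinism of the training loop on a small run
  ds <- desk_dataset("default", 200, 1)
  fit_a <- train_model(spec_short(), ds[1:40], ds[41:60], epochs = 2,
                       patience = 2, seed = 9)
  fit_b <- train_model(spec_short(), ds[1:40], ds[41:60], epochs = 2,
                       patience = 2, seed = 9)
  expect_identical(fit_a$history, fit_b$history)
  expect_identical(fit_a$model$conv[[1]]$W, fit_b$model$conv[[1]]$W)
})

test_that("shuffled labels give chance-level accuracy", {
  ds <- desk_dataset("default", 200, 1)     # non-AF block, then AF block
  train_idx <- c(1:75, 201:275)
  val_idx <- c(76:100, 276:300)
  eval_idx <- c(101:200, 301:400)           # balanced, disjoint from training
  set.seed(31)
  shuffled <- ds[c(train_idx, val_idx)]
  labs <- sample(vapply(shuffled, function(r) r$label, character(1)))
  for (i in seq_along(shuffled)) shuffled[[i]]$label <- labs[i]
  fit <- train_model(spec_short(), shuffled[1:150], shuffled[151:200],
                     epochs = 5, patience = 5, seed = 2)
  acc <- evaluate(fit$model, ds[eval_idx])$accuracy
  expect_lt(abs(acc - 50), 5)
})

test_that("ensemble weight optimization behaves at the boundaries", {
  pair <- trained_pair("default", seed = 1)
  models <- list(short = pair$short$model, long = pair$long$model)

  # identical models: F1 constant in the weight; neutral 1.0 returned
  w_same <- optimize_ensemble_weight(
    list(list(short = models$short, long = models$short)), list(pair$val),
    weight_grid = seq(0.25, 3, by = 0.25))
  expect_equal(w_same$w_long, 1)

  # misleading short model + competent long model: optimal weight favors long
  bad_short <- models$short
  bad_short$dense$W <- bad_short$dense$W[2:1, ]    # swap class read-outs
  w_dir <- optimize_ensemble_weight(
    list(list(short = bad_short, long = models$long)), list(pair$val),
    weight_grid = seq(0.25, 3, by = 0.25))
  expect_gt(w_dir$w_long, 1)

  # degenerate single-class fold is skipped with a warning
  one_class <- Filter(function(r) r$label == "AF", pair$val)
  expect_warning(
    w2 <- optimize_ensemble_weight(
      list(list(short = models$short, long = models$long),
           list(short = models$short, long = models$long)),
      list(pair$val, one_class), weight_grid = c(0.5, 1, 2)),
    "single class")
  expect_true(is.finite(w2$w_long))
})
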