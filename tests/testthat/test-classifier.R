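# Network architecture, training mechanics and the dataset splitter.

test_that("default architecture reproduces the reference shape chain", {
  shapes <- model_shapes(model_config(7, 5))
  expect_identical(shapes$input, c(3L, 128L, 128L))
  expect_identical(shapes$conv1, c(64L, 128L, 128L))
  expect_identical(shapes$pool1, c(64L, 64L, 64L))
  expect_identical(shapes$conv2, c(128L, 64L, 64L))
  expect_identical(shapes$pool2, c(128L, 32L, 32L))

  # k = 5, two blocks: 32 -> 16 -> 8
  expect_identical(model_shapes(model_config(5, 3))$pool2, c(128L, 8L, 8L))
  # incompatible depth for the grid side
  expect_error(model_config(1, 2, conv_channels = c(8, 16, 32)),
               "divisible")
})

test_that("softmax outputs form a probability simplex for random weights", {
  cfg <- model_config(3, 4, conv_channels = c(4L, 8L), fc_units = 16L)
  set.seed(3)
  params <- cgrnet:::nn_init_params(cfg)
  X <- array(runif(8 * 8 * 3 * 6), dim = c(8, 8, 3, 6))
  P <- cgrnet:::nn_forward(params, X, cfg)$probs
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
})

test_that("training is reproducible under a fixed seed", {
  specs <- make_class_specs(2, separation = 1, seed = 5)
  ds <- sample_sequences(specs, n_per_class = 10, length = 200, seed = 5)
  tensors <- featurize(ds$sequences, k = 2)
  fit1 <- cgrnet(tensors, ds$labels, conv_channels = c(8L, 16L),
                 fc_units = 32L, max_epochs = 4, batch_size = 8, seed = 9)
  fit2 <- cgrnet(tensors, ds$labels, conv_channels = c(8L, 16L),
                 fc_units = 32L, max_epochs = 4, batch_size = 8, seed = 9)
  expect_identical(predict(fit1, tensors, type = "prob"),
                   predict(fit2, tensors, type = "prob"))
  expect_identical(fit1$history, fit2$history)
})

test_that("optimization drives the loss down when overfitting one batch", {
  specs <- make_class_specs(2, separation = 0.5, seed = 2)
  ds <- sample_sequences(specs, n_per_class = 8, length = 150, seed = 2)
  tensors <- featurize(ds$sequences, k = 2)
  fit <- cgrnet(tensors, ds$labels, conv_channels = c(8L, 16L),
                fc_units = 32L, max_epochs = 50, batch_size = 16,
                validation = 0, seed = 4)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("prediction is ranked by probability with index tie-break", {
  specs <- make_class_specs(3, separation = 1, seed = 8)
  ds <- sample_sequences(specs, n_per_class = 8, length = 200, seed = 8)
  tensors <- featurize(ds$sequences, k = 2)
  fit <- cgrnet(tensors, ds$labels, conv_channels = c(8L, 16L),
                fc_units = 32L, max_epochs = 3, batch_size = 8, seed = 1)
  P <- predict(fit, tensors, type = "prob")
  R <- predict(fit, tensors, type = "rank")
  cl <- predict(fit, tensors, type = "class")
  expect_identical(unname(R[, 1]), unname(cl))
  for (i in seq_len(nrow(P))) {
    expect_identical(unname(R[i, 1]), fit$levels[which.max(P[i, ])])
    expect_true(all(diff(P[i, R[i, ]]) <= 0))
  }
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("degenerate labels and mismatched tensors are rejected", {
  specs <- make_class_specs(2, separation = 1, seed = 1)
  ds <- sample_sequences(specs, n_per_class = 6, length = 100, seed = 1)
  tensors <- featurize(ds$sequences, k = 2)
  expect_error(cgrnet(tensors, rep("only", length(tensors))),
               "single class")
  fit <- cgrnet(tensors, ds$labels, conv_channels = c(8L, 16L),
                fc_units = 32L, max_epochs = 2, batch_size = 8, seed = 1)
  wrong_k <- featurize(ds$sequences[1], k = 3)
  expect_error(predict(fit, wrong_k), "expects k")
})

test_that("the 8:1:1 splitter is exact, exhaustive and seeded", {
  sp <- split_dataset(1:100, seed = 1)
  expect_identical(unname(lengths(sp)), c(80L, 10L, 10L))
  expect_identical(sort(unname(unlist(sp))), 1:100)

  sp2 <- split_dataset(seq_len(8595), seed = 3)
  expect_identical(unname(lengths(sp2)), c(6876L, 859L, 860L))

  expect_identical(split_dataset(1:50, seed = 7), split_dataset(1:50, seed = 7))
  expect_false(identical(split_dataset(1:50, seed = 7),
                         split_dataset(1:50, seed = 8)))
  expect_error(split_dataset(1:5), "at least 10")
})

test_that("model checkpoints round-trip and predict identically", {
  specs <- make_class_specs(2, separation = 1, seed = 6)
  ds <- sample_sequences(specs, n_per_class = 6, length = 100, seed = 6)
  tensors <- featurize(ds$sequences, k = 2)
  fit <- cgrnet(tensors, ds$labels, conv_channels = c(8L, 16L),
                fc_units = 32L, max_epochs = 2, batch_size = 8, seed = 1)
  f <- tempfile(fileext = ".rds")
  save_cgrnet(fit, f)
  fit2 <- load_cgrnet(f)
  expect_identical(predict(fit, tensors, type = "prob"),
                   predict(fit2, tensors, type = "prob"))
  expect_identical(fit2$levels, fit$levels)
})
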