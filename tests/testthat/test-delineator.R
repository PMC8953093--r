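test_that("model construction validates arguments and reports shapes", {
  expect_error(build_model(conv_filters = c(8L, 0L)), "positive")
  expect_error(build_model(units_per_direction = 0L), "positive")
  expect_error(build_model(n_classes = 1L), ">= 2")
  m <- build_model()
  sh <- layer_shapes(m)
  expect_equal(sh$width, c(8L, 16L, 32L, 64L, 1024L, 5L))
  expect_equal(sh$layer[1:4], paste0("conv", 1:4))
})

test_that("a conv-free model starts with the recurrent layer", {
  m <- build_model(conv_filters = integer(0), units_per_direction = 6L,
                   window_len = 20L, seed = 3L)
  sh <- layer_shapes(m)
  expect_equal(sh$layer[[1L]], "bilstm")
  expect_equal(sh$width, c(12L, 5L))
  p <- predict(m, matrix(rnorm(20), 20, 1), allow_untrained = TRUE,
               type = "prob")
  expect_equal(dim(p$probabilities), c(20L, 5L, 1L))
  expect_equal(rowSums(p$probabilities[, , 1L]), rep(1, 20),
               tolerance = 1e-6)
})

test_that("the compiled forward pass matches a hand-coded evaluation", {
  # 1-filter, 1-unit toy
  m1 <- build_model(conv_filters = 1L, units_per_direction = 1L,
                    window_len = 8L, seed = 5L)
  x <- c(0.3, -1.2, 0.8, 0.0, 2.1, -0.4, 0.6, -0.9)
  got <- ecgdelin:::cpp_nn_forward_layers(m1$params, x)
  want <- ref_nn_forward(m1$params, x)
  expect_lt(max(abs(got$probs - want)), 1e-6)
  # a wider toy with two conv layers
  m2 <- build_model(conv_filters = c(3L, 4L), units_per_direction = 6L,
                    window_len = 15L, seed = 6L)
  x2 <- sin(seq(0, 3, length.out = 15L))
  got2 <- ecgdelin:::cpp_nn_forward_layers(m2$params, x2)
  want2 <- ref_nn_forward(m2$params, x2)
  expect_lt(max(abs(got2$probs - want2)), 1e-6)
  # conv layers preserve length, widths follow the filter counts
  expect_equal(dim(got2$conv1), c(3L, 15L))
  expect_equal(dim(got2$conv2), c(4L, 15L))
  expect_equal(dim(got2$bilstm), c(12L, 15L))
})

test_that("prediction rows are distributions and ties break to class 0", {
  m <- build_model(conv_filters = c(2L, 3L), units_per_direction = 4L,
                   window_len = 30L, seed = 9L)
  X <- matrix(rnorm(30 * 3), 30, 3)
  p <- predict(m, X, allow_untrained = TRUE, type = "prob")
  for (i in 1:3) {
    expect_equal(rowSums(p$probabilities[, , i]), rep(1, 30),
                 tolerance = 1e-6)
    expect_true(all(p$probabilities[, , i] >= 0))
  }
  expect_error(predict(m, X), "untrained")
  expect_error(predict(m, matrix(0, 10, 1), allow_untrained = TRUE),
               "expects")
  # zeroed head -> exactly uniform rows -> argmax tie resolves to class 0
  m$params$Wd[] <- 0
  m$params$bd[] <- 0
  p0 <- predict(m, X, allow_untrained = TRUE)
  expect_true(all(p0$predicted == 0L))
})

test_that("training history, determinism and validation accounting", {
  tw <- synth_training_windows(12L, seed = 7L)
  m <- build_model(conv_filters = c(2L, 4L), units_per_direction = 8L,
                   seed = 1L)
  cfg1 <- train_config(learning_rate = 1e-3, epochs = 1L, batch_size = 4L,
                       seed = 2L, validation_fraction = 0.25)
  f1 <- train_delineator(m, tw$windows, cfg1)
  expect_equal(nrow(f1$history), 1L)
  expect_true(f1$trained)
  expect_equal(f1$validation$n_windows, 3L)
  cfg <- train_config(learning_rate = 1e-3, epochs = 3L, batch_size = 4L,
                      seed = 2L, validation_fraction = 0)
  fa <- train_delineator(m, tw$windows, cfg)
  fb <- train_delineator(m, tw$windows, cfg)
  expect_equal(tail(fa$history$loss, 1L), tail(fb$history$loss, 1L),
               tolerance = 1e-6)
  expect_error(train_delineator(m, tw$windows[1L], cfg), "two windows")
})

test_that("a small model memorizes a handful of windows", {
  tw <- synth_training_windows(8L, seed = 15L)
  m <- build_model(conv_filters = c(4L, 8L), units_per_direction = 32L,
                   seed = 4L)
  cfg <- train_config(learning_rate = 3e-3, epochs = 200L, batch_size = 2L,
                      seed = 4L, validation_fraction = 0)
  fit <- train_delineator(m, tw$windows, cfg)
  expect_gte(tail(fit$history$accuracy, 1L), 0.99)
  pred <- predict(fit, tw$windows)
  truth <- vapply(tw$windows, function(w) w$mask, integer(370L))
  expect_gte(mean(pred$predicted == truth), 0.99)
})

test_that("fiducials are extracted from mask runs with duration gating", {
  expect_equal(nrow(fiducials_from_mask(rep(3L, 50L), numeric(50L), 250)),
               0L)
  mask <- rep(3L, 200L)
  mask[101:130] <- 1L  # run [100, 130)
  samples <- numeric(200L)
  samples[[115L]] <- 1.4
  fd <- fiducials_from_mask(mask, samples, 250)
  expect_equal(fd$wave, "QRS")
  expect_equal(fd$onset, 100L)
  expect_equal(fd$offset, 130L)
  expect_equal(fd$duration_s, 0.12)
  expect_equal(fd$peak_index, 114L)
  # sub-0.02 s blips are discarded
  mask[[5L]] <- 0L
  fd2 <- fiducials_from_mask(mask, samples, 250)
  expect_equal(fd2$wave, "QRS")
})
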