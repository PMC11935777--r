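test_that("standardizer centers and scales training rows only", {
  x <- cbind(const = rep(5, 4), two = c(0, 2, 0, 2), ramp = 1:4)
  s <- fit_standardizer(x)
  xs <- apply_standardizer(s, x)
  expect_equal(unname(xs[, 1]), rep(0, 4))          # constant -> 0
  expect_equal(unname(xs[1:2, 2]), c(-1, 1))
  expect_equal(colMeans(xs), c(const = 0, two = 0, ramp = 0), tolerance = 1e-6)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(unname(apply(xs[, 2:3], 2, pop_sd)), c(1, 1), tolerance = 1e-9)

  # held-out rows keep training statistics: their mean is not recentred
  held <- cbind(const = rep(5, 3), two = rep(2, 3), ramp = 7:9)
  hs <- apply_standardizer(s, held)
  expect_gt(abs(mean(hs[, "ramp"])), 1)

  expect_error(fit_standardizer(x[1, , drop = FALSE]),
               class = "ppi_input_error")
  expect_error(apply_standardizer(s, x[, 1:2]), class = "ppi_dimension_error")
})

test_that("two-point column standardizes to -1, +1", {
  s <- fit_standardizer(matrix(c(0, 2), ncol = 1))
  expect_equal(unname(apply_standardizer(s, matrix(c(0, 2), ncol = 1))[, 1]),
               c(-1, 1), tolerance = 1e-12)
})

test_that("parameter count matches the closed form for any architecture", {
  for (hs in list(4L, c(8L, 3L), c(512L, 256L, 128L, 64L), c(5L, 5L, 5L))) {
    m <- build_classifier(10L, model_config(hidden_sizes = hs))
    expect_equal(ppitriad:::.mlp_count_actual(m),
                 mlp_parameter_count(10L, hs))
  }
  # dense-only arithmetic for one hidden layer: 10*4+4 weights+biases = 49
  # with the 2*4 batch-norm affine terms on top
  expect_equal(mlp_parameter_count(10, 4), 49 + 8)
})

test_that("the default architecture has four hidden blocks and sigmoid output", {
  m <- build_classifier(20L, model_config())
  expect_length(m$layers, 4L)
  expect_equal(vapply(m$layers, function(l) ncol(l$W), integer(1)),
               c(512L, 256L, 128L, 64L))
  for (l in m$layers) {
    expect_length(l$gamma, length(l$beta))
    expect_length(l$r_mean, length(l$r_var))
  }
  # untrained output is a valid probability
  p <- ppitriad:::.mlp_forward(m, matrix(rnorm(100), 5, 20), m$config)$p
  expect_true(all(p > 0 & p < 1))
  expect_error(build_classifier(0L), class = "ppi_input_error")
})

test_that("training separates Gaussian clouds and is seed-deterministic", {
  d <- gaussian_clouds(400, d = 10, sep = 3, seed = 1)
  cfg <- model_config(hidden_sizes = c(16L, 8L), max_epochs = 30L,
                      early_stop_patience = 6L, batch_size = 32L, seed = 9L)
  split <- c(rep(TRUE, 150), rep(FALSE, 50), rep(TRUE, 150), rep(FALSE, 50))
  fit <- train_classifier(x = d$x[split, ], y = d$y[split], config = cfg)
  pred <- predict(fit, d$x[!split, ])
  acc <- mean(pred$label == d$y[!split])
  expect_gte(acc, 0.95)

  # training loss decreases over the first epochs on a learnable problem
  h <- tidy(fit)
  expect_lt(h$train_loss[5], h$train_loss[1])
  # checkpoint: restored validation loss <= last epoch's
  expect_lte(fit$best_val_loss, h$val_loss[nrow(h)])

  fit2 <- train_classifier(x = d$x[split, ], y = d$y[split], config = cfg)
  expect_identical(fit$layers, fit2$layers)
  expect_identical(fit$out, fit2$out)
})

test_that("permuted labels yield chance-level held-out accuracy", {
  d <- gaussian_clouds(400, d = 10, sep = 3, seed = 2)
  set.seed(21)
  y_perm <- sample(d$y)
  cfg <- model_config(hidden_sizes = c(16L, 8L), max_epochs = 20L,
                      early_stop_patience = 5L, batch_size = 32L, seed = 3L)
  fit <- train_classifier(x = d$x[1:200, ], y = y_perm[1:200], config = cfg)
  acc <- mean(predict(fit, d$x[201:400, ])$label == y_perm[201:400])
  expect_gte(acc, 0.5 - 0.08)
  expect_lte(acc, 0.5 + 0.08)
})

test_that("training input contracts are enforced", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(train_classifier(x = x, y = rep(1L, 20)),
               class = "ppi_training_error")
  expect_error(train_classifier(x = x, y = rep(c(0L, 1L), 5)),
               class = "ppi_input_error")
})

test_that("prediction applies the threshold-at-0.5-to-positive convention", {
  d <- gaussian_clouds(60, d = 4, sep = 4, seed = 5)
  cfg <- model_config(hidden_sizes = 8L, max_epochs = 5L, seed = 1L)
  fit <- train_classifier(x = d$x, y = d$y, config = cfg)
  pred <- predict(fit, d$x)
  expect_equal(nrow(pred), nrow(d$x))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_equal(pred$label, as.integer(pred$prob >= 0.5))
  # purity of inference
  expect_identical(pred, predict(fit, d$x))
  expect_error(predict(fit, d$x[, 1:2]), class = "ppi_dimension_error")
})

test_that("learning-rate reduction fires after stagnant epochs", {
  d <- gaussian_clouds(80, d = 4, sep = 0, seed = 6)  # nothing to learn
  cfg <- model_config(hidden_sizes = 4L, max_epochs = 40L,
                      early_stop_patience = 30L, lr_reduce_patience = 3L,
                      lr_reduce_factor = 0.5, seed = 2L)
  fit <- train_classifier(x = d$x, y = d$y, config = cfg)
  h <- tidy(fit)
  expect_lt(min(h$learning_rate), cfg$learning_rate)
})

test_that("a trained model survives a save/load round trip", {
  d <- gaussian_clouds(60, d = 6, sep = 3, seed = 8)
  cfg <- model_config(hidden_sizes = c(8L, 4L), max_epochs = 8L, seed = 4L)
  fit <- train_classifier(x = d$x, y = d$y, config = cfg)
  dir <- withr::local_tempdir()
  save_ppi_model(fit, dir, force = TRUE)
  back <- load_ppi_model(dir)
  expect_equal(predict(back, d$x)$prob, predict(fit, d$x)$prob,
               tolerance = 1e-9)
  g <- glance(back)
  expect_equal(g$n_parameters, mlp_parameter_count(6, c(8L, 4L)))
})
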