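# Augmentation, schedule, early stopping, and training behaviour.

make_tiny_fitdata <- function(n, seed, grid = c(16L, 16L, 16L)) {
  cases <- make_training_pairs(n, grid_shape = grid, voxel_size_mm = 18,
                               acq = acq_settings(count_scale = 1e5),
                               seed = seed)
  prepare_cases(cases, "PS", "log_max")
}

test_that("flip augmentation is a consistent involution", {
  set.seed(41)
  x <- array(runif(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  y <- array(runif(4 * 4 * 4), c(4, 4, 4))
  a1 <- augment_flip(list(x = x, y = y), seed = 3)
  a2 <- augment_flip(list(x = a1$x, y = a1$y), axes = a1$axes)
  expect_identical(a2$x, x)
  expect_identical(a2$y, y)
  # label and input flipped by the same axes: a marked voxel tracks
  xm <- x; xm[1, 2, 3, 1] <- 99
  ym <- y; ym[1, 2, 3] <- 99
  af <- augment_flip(list(x = xm, y = ym), axes = c(1, 3))
  expect_equal(which(af$x[, , , 1] == 99), which(af$y == 99))
  # deterministic axis mask under a fixed seed
  b1 <- augment_flip(list(x = x, y = y), seed = 12)
  b2 <- augment_flip(list(x = x, y = y), seed = 12)
  expect_identical(b1$axes, b2$axes)
})

test_that("learning rate decays exponentially per epoch and history is complete", {
  dat <- make_tiny_fitdata(3, seed = 42)
  cfg <- net_config(in_channels = 2, base_filters = 2, depth = 2)
  gen <- build_generator(cfg, c(16, 16, 16), seed = 1)
  fit <- train_generator(gen, dat[1:2], dat[3], train_control(
    epochs = 3, batch_size = 2, seed = 2))
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_equal(h$lr, 1e-3 * 0.96^(0:2))
  expect_true(all(diff(h$lr) < 0))
  fit1 <- train_generator(gen, dat[1:2], dat[3],
                          train_control(epochs = 1, seed = 2))
  expect_equal(nrow(fit1$history), 1)
})

test_that("training is reproducible and restores best-validation weights", {
  dat <- make_tiny_fitdata(4, seed = 43)
  cfg <- net_config(in_channels = 2, base_filters = 2, depth = 2)
  gen <- build_generator(cfg, c(16, 16, 16), seed = 5)
  ctl <- train_control(epochs = 4, batch_size = 2, seed = 7)
  f1 <- train_generator(gen, dat[1:3], dat[4], ctl)
  f2 <- train_generator(gen, dat[1:3], dat[4], ctl)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
  expect_identical(f1$generator$par, f2$generator$par)
})

test_that("early stopping never triggers before the warm-up period", {
  dat <- make_tiny_fitdata(3, seed = 44)
  cfg <- net_config(in_channels = 2, base_filters = 2, depth = 2)
  gen <- build_generator(cfg, c(16, 16, 16), seed = 1)
  # patience 1 with warm-up 5: at least 6 epochs must run even if the
  # validation loss never improves after epoch 1
  fit <- train_generator(gen, dat[1:2], dat[3], train_control(
    epochs = 8, batch_size = 2, patience = 1, warmup_epochs = 5, seed = 3))
  expect_gte(nrow(fit$history), 6)
})

test_that("a tiny generator overfits a single phantom pair", {
  dat <- make_tiny_fitdata(1, seed = 45, grid = c(32L, 32L, 32L))
  cfg <- net_config(in_channels = 2, base_filters = 8, depth = 2)
  gen <- build_generator(cfg, c(32, 32, 32), seed = 2)
  fit <- train_generator(gen, dat, dat, train_control(
    epochs = 50, batch_size = 1, augment = FALSE, patience = 50, seed = 4))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.10 * h$train_loss[1])
})

test_that("ablation tables carry labels and reproduce across reruns", {
  cases <- make_training_pairs(6, grid_shape = c(16L, 16L, 16L),
                               voxel_size_mm = 18,
                               acq = acq_settings(count_scale = 1e5),
                               seed = 46)
  cfgs <- list(list(input = "PS", normalization = "log_max",
                    loss = loss_config(omega = 0),
                    upsampling = "nearest_interp", label = "L1"))
  ctl <- train_control(epochs = 1, batch_size = 2, seed = 3)
  t1 <- run_ablation(cases[1:3], cases[4], cases[5:6], cfgs,
                     base_filters = 2, depth = 2, control = ctl, seed = 1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$loss, "L1")
  expect_equal(t1$input, "PS")
  expect_equal(t1$n_cases, 2)
  expect_true(all(c("r_squared_mean", "mse_sd", "nmae_percent_mean")
                  %in% names(t1)))
  t2 <- run_ablation(cases[1:3], cases[4], cases[5:6], cfgs,
                     base_filters = 2, depth = 2, control = ctl, seed = 1)
  expect_identical(t1, t2)
})
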