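test_that("the training loss follows its closed form and a brute-force oracle", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  # one sample, one time point, 2 mV error: L = 1/2 * 4
  expect_equal(mse_loss(matrix(5), matrix(3)), 2)
  set.seed(31)
  pred <- matrix(rnorm(7 * 11), 7)
  tgt <- matrix(rnorm(7 * 11), 7)
  brute <- 0
  for (i in 1:7) for (k in 1:11) brute <- brute + (pred[i, k] - tgt[i, k])^2
  brute <- brute / (2 * 11)
  expect_equal(mse_loss(pred, tgt), brute, tolerance = 1e-10)
  expect_gt(mse_loss(pred, tgt), 0)
  expect_error(mse_loss(1:3, 1:4), "length")
})

test_that("zero epochs return the initialized weights unchanged", {
  ds <- tiny_dataset()
  cfg <- training_config(epochs = 0, batch_from = 4, batch_to = 4,
                         seed = 5)
  w0 <- init_emulator_weights(seed = cfg$init_seed)
  w <- train_emulator(ds, cfg)
  for (l in seq_along(w0$theta1))
    expect_identical(w$theta1[[l]]$W, w0$theta1[[l]]$W)
  for (l in seq_along(w0$theta2))
    expect_identical(w$theta2[[l]]$W, w0$theta2[[l]]$W)
})

test_that("training is reproducible and its loss decreases", {
  ds <- tiny_dataset()
  cfg <- training_config(epochs = 40, batch_from = 9, batch_to = 9,
                         tfrac_from = 1 / 16, tfrac_to = 1 / 16,
                         lr = 2e-3, seed = 13, val_every = 20)
  w1 <- train_emulator(ds, cfg)
  w2 <- train_emulator(ds, cfg)
  log1 <- attr(w1, "log"); log2 <- attr(w2, "log")
  expect_identical(log1$train_loss, log2$train_loss)
  # decreasing in moving average: late-window mean well below early-window
  expect_lt(mean(tail(log1$train_loss, 10)), mean(head(log1$train_loss, 10)))
})

test_that("a tiny corpus can be memorized", {
  ds <- tiny_dataset()
  ds$split <- rep("train", nrow(ds$vm))          # use all 12 samples
  cfg <- training_config(epochs = 2000, batch_from = 12, batch_to = 12,
                         tfrac_from = 1 / 16, tfrac_to = 1 / 16,
                         lr = 5e-3, lr_final = 5e-4, seed = 17, val_every = 1e9)
  w <- train_emulator(ds, cfg)
  r <- validation_rmse(w, list(vm = ds$vm, conductances = ds$conductances),
                       ds$grid)
  w0 <- init_emulator_weights(seed = cfg$init_seed)
  r0 <- validation_rmse(w0, list(vm = ds$vm, conductances = ds$conductances),
                        ds$grid)
  # the residual concentrates in the 2 ms depolarization spike, whose
  # high-resolution carving through the polynomial time basis only
  # completes on much longer schedules; the repolarization is essentially
  # memorized at this budget
  expect_lt(r, 3)
  expect_lt(r, r0 / 20)
})

test_that("the fused training loop reproduces a reference full-batch step", {
  # with batch = n and the full time grid, the subset draws select
  # everything, so one fused epoch equals one deterministic Adam step and
  # can be compared against the step-by-step reference path
  ds <- tiny_dataset()
  ds$split <- rep("train", nrow(ds$vm))
  n <- nrow(ds$vm)
  cfg_fused <- training_config(epochs = 1, batch_from = n, batch_to = n,
                               tfrac_from = 1, tfrac_to = 1, lr = 1e-3,
                               seed = 3, val_every = 1e9,
                               precision = "single")
  cfg_ref <- training_config(epochs = 1, batch_from = n, batch_to = n,
                             tfrac_from = 1, tfrac_to = 1, lr = 1e-3,
                             seed = 3, val_every = 1e9,
                             precision = "double")
  w1 <- train_emulator(ds, cfg_fused)
  w2 <- train_emulator(ds, cfg_ref)
  for (l in seq_along(w1$theta2)) {
    d <- max(abs(w1$theta2[[l]]$W - w2$theta2[[l]]$W))
    expect_lt(d / (max(abs(w2$theta2[[l]]$W)) + 1e-12), 1e-3)
  }
  expect_equal(attr(w1, "log")$train_loss, attr(w2, "log")$train_loss,
               tolerance = 1e-4)
})

test_that("random time subsets give unbiased gradient estimates", {
  ds <- tiny_dataset()
  w <- tiny_weights()
  Xn <- t(apply(ds$conductances, 1, normalize_conductances))
  Tn <- length(ds$grid)
  full <- emu_eval(w, Xn, ds$grid, target = ds$vm, want_grads = TRUE)
  pick <- function(res) as.numeric(res$grads2[[2]]$W)
  ref <- pick(full)
  set.seed(23)
  acc <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    tsel <- sort(sample.int(Tn, Tn %/% 16))
    sub <- emu_eval(w, Xn, ds$grid[tsel], target = ds$vm[, tsel, drop = FALSE],
                    want_grads = TRUE)
    acc <- acc + pick(sub)
  }
  acc <- acc / reps
  # relative deviation of the averaged subset gradient from the full one
  expect_lt(sqrt(sum((acc - ref)^2)) / sqrt(sum(ref^2)), 0.05)
})
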