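# fitting tests run against untrained (randomly initialized) weights: the
# fitter only requires a differentiable emulator, and emulated targets give
# a known ground truth

fit_grid <- function() canonical_grid()[seq(1, 4191, by = 20)]

test_that("fitting an emulated target from the truth stays at the truth", {
  w <- tiny_weights()
  x_star <- runif(9, -0.3, 0.3)
  tgt <- emulate_ap(x_star, fit_grid(), w)
  cfg <- fit_config(iterations = 50, lr = 1e-3)
  fit <- fit_ap(tgt, x_star, x_star, w, cfg)
  expect_lt(max(abs(fit$x_hat - x_star)), 0.02)
  expect_lt(fit$rmse, 0.05)
  expect_lt(fit$objective, 0.05)
})

test_that("an overwhelming prior pins the estimate to the prior center", {
  w <- tiny_weights()
  set.seed(3)
  x_star <- runif(9, -0.3, 0.3)
  x_prior <- rep(0.1, 9)
  tgt <- emulate_ap(x_star, fit_grid(), w)
  fit <- fit_ap(tgt, x_prior, x_prior, w,
                fit_config(lambda_x0 = 1e6, iterations = 300, lr = 5e-3))
  expect_lt(max(abs(fit$x_hat - x_prior)), 1e-3)
})

test_that("increasing the prior weight pulls the estimate monotonically", {
  w <- tiny_weights()
  set.seed(8)
  x_star <- runif(9, -0.35, 0.35)
  tgt <- emulate_ap(x_star, fit_grid(), w)
  d <- sapply(c(0.1, 1, 10, 100), function(lam) {
    fit <- suppressWarnings(
      fit_ap(tgt, rep(0, 9), rep(0, 9), w,
             fit_config(lambda_x0 = lam, iterations = 400, lr = 5e-3)))
    sqrt(sum(fit$x_hat^2))          # distance from the prior center 0
  })
  expect_true(all(diff(d) <= 1e-6))
})

test_that("every estimate respects the feasible box", {
  w <- tiny_weights()
  set.seed(12)
  # targets emulated from corner points push the fit against the bounds
  x_star <- rep(0.5, 9)
  tgt <- emulate_ap(x_star, fit_grid(), w)
  fit <- fit_ap(tgt, rep(0, 9), rep(0, 9), w,
                fit_config(lambda_x0 = 0, iterations = 200, lr = 0.02))
  expect_true(all(fit$x_hat >= -0.5 & fit$x_hat <= 0.5))
})

test_that("a time-shifted target is absorbed by the offset parameter", {
  w <- tiny_weights()
  set.seed(14)
  x_star <- runif(9, -0.2, 0.2)
  grid <- canonical_grid()[canonical_grid() >= -5 & canonical_grid() <= 900]
  grid <- grid[seq(1, length(grid), by = 15)]
  shift <- 3
  vm <- emulate_vm(x_star, grid - shift, w)
  fit <- fit_ap(ap_trace(grid, vm), x_star, x_star, w,
                fit_config(iterations = 400, lr = 1e-3, lr_t0 = 0.05))
  expect_equal(unname(fit$t0), shift, tolerance = 0.25)
})

test_that("control and drug estimation wire their priors as documented", {
  w <- tiny_weights()
  tgt0 <- emulate_ap(rep(0, 9), fit_grid(), w)
  fit0 <- estimate_control(tgt0, w, fit_config(iterations = 120, lr = 2e-3))
  expect_lt(max(abs(fit0$x_hat)), 0.05)
  # identical drugged trace: estimate stays at the control estimate
  fitd <- estimate_drug(tgt0, fit0$x_hat, w,
                        fit_config(iterations = 120, lr = 2e-3))
  expect_lt(max(abs(fitd$x_hat - fit0$x_hat)), 0.02)
  # determinism
  fit0b <- estimate_control(tgt0, w, fit_config(iterations = 120, lr = 2e-3))
  expect_identical(fit0$x_hat, fit0b$x_hat)
})

test_that("scaling factors are element-wise conductance ratios", {
  g_ref <- conductance_set()
  xc <- rep(0, 9)
  expect_equal(unclass(scaling_factors(xc, xc, g_ref)), rep(1, 9),
               ignore_attr = TRUE)
  # gKr block to 5 %: normalized drug coordinate 0.05/2 - 0.5
  xd <- xc; xd[5] <- 0.05 / 2 - 0.5
  s <- scaling_factors(xc, xd, g_ref)
  expect_equal(unname(s["gKr"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(s[-5]), rep(1, 8))
  # independent recomputation
  gc_ <- 2 * 1 * (xc + 0.5); gd_ <- 2 * 1 * (xd + 0.5)
  expect_equal(unclass(s), gd_ / gc_, ignore_attr = TRUE)
  # zero control conductance is an explicit error naming the coordinate
  xz <- xc; xz[5] <- -0.5
  expect_error(scaling_factors(xz, xd, g_ref), "gKr")
})
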