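test_that("conductance normalization is the stated bijection", {
  g_ref <- conductance_set()
  expect_equal(unname(normalize_conductances(conductance_set(), g_ref)),
               rep(0, 9))
  expect_equal(unname(normalize_conductances(rep(0, 9), g_ref)), rep(-0.5, 9))
  expect_equal(unname(normalize_conductances(rep(2, 9), g_ref)), rep(0.5, 9))
  set.seed(5)
  for (k in 1:20) {
    g <- as_conductance_set(runif(9, 0, 2))
    gr <- as_conductance_set(runif(9, 0.5, 1.5))
    x <- suppressWarnings(tryCatch(normalize_conductances(g, gr),
                                   error = function(e) NULL))
    if (is.null(x)) next                        # outside [-0.5, 0.5] for gr
    expect_equal(unclass(denormalize_conductances(x, gr)), unclass(g),
                 tolerance = 1e-12)
  }
  expect_error(normalize_conductances(conductance_set(), rep(0, 9)), "positive")
})

test_that("the depolarization helper realizes its closed form", {
  w <- tiny_weights()
  # silence the decoder and pin the encoder output so that
  # (d1, d2, d3) = (2, 10, 100) and the latent code is all zero
  for (l in seq_along(w$theta2)) {
    w$theta2[[l]]$W[] <- 0; w$theta2[[l]]$b[] <- 0
  }
  for (l in seq_along(w$theta1)) {
    w$theta1[[l]]$W[] <- 0; w$theta1[[l]]$b[] <- 0
  }
  inv_softplus <- function(y) log(expm1(y))
  w$theta1[[4]]$b <- c(rep(0, 256), inv_softplus(2), 10, inv_softplus(1))
  x <- rep(0, 9)
  expect_equal(emulate_vm(x, 10, w), 0, tolerance = 1e-9)
  expect_equal(emulate_vm(x, 1000, w), 50, tolerance = 1e-9)
  expect_equal(emulate_vm(x, -10, w), -50, tolerance = 1e-6)
  lat <- encode(x, w)
  expect_equal(lat$d1, 2, tolerance = 1e-12)
  expect_equal(lat$d2, 10)
  expect_equal(lat$d3, 100, tolerance = 1e-12)
  expect_equal(as.numeric(lat$theta), rep(0, 256))
})

test_that("emulation decomposes into decoder output plus tanh term", {
  w <- tiny_weights()
  x <- runif(9, -0.4, 0.4)
  tt <- c(-10, 0.7, 33, 512, 1000)
  lat <- encode(x, w)
  depol <- (lat$d3 / 2) * tanh((lat$d1 / 2) * (tt - lat$d2))
  full <- emulate_vm(x, tt, w)
  # the decoder-only part, via the reference forward pass
  f <- emu_forward(w, matrix(x, 1), tt, keep_cache = FALSE)
  expect_equal(full, as.numeric(f$pred), tolerance = 1e-12)
  expect_equal(as.numeric(f$pred) - as.numeric(depol),
               full - as.numeric(depol), tolerance = 1e-12)
})

test_that("the C++ evaluation path matches the reference implementation", {
  w <- tiny_weights()
  set.seed(9)
  X <- matrix(runif(4 * 9, -0.5, 0.5), 4)
  tt <- sort(runif(25, -10, 1000))
  tgt <- matrix(rnorm(100), 4)
  fwd <- emu_forward(w, X, tt)
  err <- fwd$pred - tgt
  ref <- emu_backward(w, fwd, err / length(tt), want_t_grad = TRUE)
  res <- emu_eval(w, X, tt, target = tgt, want_grads = TRUE,
                  want_x_grad = TRUE, want_t_grad = TRUE)
  expect_equal(res$pred, fwd$pred, tolerance = 1e-12)
  expect_equal(res$loss, sum(err^2) / (2 * length(tt)), tolerance = 1e-12)
  expect_equal(res$dX, ref$dX, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.numeric(res$dt), as.numeric(ref$dt), tolerance = 1e-10)
  for (l in seq_along(w$theta1)) {
    expect_equal(res$grads1[[l]]$W, ref$grads1[[l]]$W, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(as.numeric(res$grads1[[l]]$b), as.numeric(ref$grads1[[l]]$b),
                 tolerance = 1e-10)
  }
  for (l in seq_along(w$theta2))
    expect_equal(res$grads2[[l]]$W, ref$grads2[[l]]$W, tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("the single-precision path agrees with the double path", {
  w <- tiny_weights()
  set.seed(33)
  X <- matrix(runif(3 * 9, -0.5, 0.5), 3)
  tt <- sort(runif(30, -10, 1000))
  tgt <- matrix(rnorm(90), 3)
  rd <- emu_eval(w, X, tt, target = tgt, want_grads = TRUE,
                 want_x_grad = TRUE)
  rs <- emu_eval(w, X, tt, target = tgt, want_grads = TRUE,
                 want_x_grad = TRUE, precision = "single")
  expect_lt(max(abs(rs$pred - rd$pred)) / max(abs(rd$pred)), 1e-5)
  expect_lt(abs(rs$loss - rd$loss) / rd$loss, 1e-4)
  rel <- max(mapply(function(a, b) max(abs(a$W - b$W)) / (max(abs(b$W)) + 1e-12),
                    rs$grads2, rd$grads2))
  expect_lt(rel, 1e-3)
})

test_that("analytic gradients match central differences", {
  w <- tiny_weights()
  set.seed(21)
  x <- runif(9, -0.4, 0.4)
  tt <- sort(runif(40, -10, 1000))
  tgt <- sin(tt / 150) * 40 - 40
  lossf <- function(xv, t0 = 0) {
    r <- emu_eval(w, matrix(xv, 1), matrix(tt - t0, 1),
                  target = matrix(tgt, 1), want_x_grad = TRUE)
    r$loss
  }
  res <- emu_eval(w, matrix(x, 1), tt, target = matrix(tgt, 1),
                  want_x_grad = TRUE, want_t_grad = TRUE)
  h <- 1e-6
  for (i in c(1, 4, 9)) {
    xp <- x; xm <- x; xp[i] <- x[i] + h; xm[i] <- x[i] - h
    fd <- (lossf(xp) - lossf(xm)) / (2 * h)
    expect_equal(res$dX[1, i], fd, tolerance = 1e-4)
  }
  fd_t <- (lossf(x, h) - lossf(x, -h)) / (2 * h)
  expect_equal(-res$dt[1], fd_t, tolerance = 1e-4)
})

test_that("emulated APs are grid-consistent and resolution independent", {
  w <- tiny_weights()
  x <- rep(0.1, 9)
  ap <- emulate_ap(x, canonical_grid(), w)
  expect_length(ap$vm, 4191)
  expect_true(all(is.finite(ap$vm)))
  sub <- canonical_grid()[seq(1, 4191, by = 10)]
  ap_sub <- emulate_ap(x, sub, w)
  expect_equal(ap_sub$vm, ap$vm[match(sub, canonical_grid())],
               tolerance = 1e-12)
  # single-time call equals the batched value
  expect_equal(emulate_vm(x, sub[5], w), ap_sub$vm[5], tolerance = 1e-12)
  expect_warning(emulate_vm(x, 1500, w), "domain")
})

test_that("weights serialize losslessly and verify their shapes", {
  w <- tiny_weights()
  path <- withr::local_tempfile(fileext = ".apw.json")
  save_weights(w, path)
  back <- load_weights(path)
  for (l in seq_along(w$theta1))
    expect_equal(back$theta1[[l]]$W, w$theta1[[l]]$W, tolerance = 1e-12)
  x <- rep(0.2, 9)
  expect_equal(emulate_vm(x, c(0, 100), back), emulate_vm(x, c(0, 100), w),
               tolerance = 1e-9)
  bad <- w
  bad$theta2[[2]]$W <- bad$theta2[[2]]$W[, 1:10]
  expect_error(check_weight_shapes(bad), "shape")
  bad2 <- w
  bad2$theta1[[1]]$W[1, 1] <- NaN
  expect_error(check_weight_shapes(bad2), "non-finite")
})
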