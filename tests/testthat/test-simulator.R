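test_that("simulation is deterministic and validates its inputs", {
  p <- fast_protocol()
  a <- simulate_ap(conductance_set(), p)
  b <- simulate_ap(conductance_set(), p)
  expect_identical(a$vm, b$vm)
  expect_identical(a$times, b$times)
  expect_error(simulate_ap(c(-0.1, rep(1, 8)), p), ">= 0")
  expect_error(conductance_set(gKr = 2.5), "<= 2")
  expect_error(simulate_ap(conductance_set(), p,
                           state = c(NaN, baseline_state()[-1])), "finite")
})

test_that("the resting state is stable without stimulation", {
  p <- pacing_protocol(stim_amplitude = 0, n_beats = 1, ss_tol = 0)
  tr <- simulate_ap(conductance_set(), p)
  expect_lt(max(abs(tr$vm - tr$vm[1])), 1)
})

test_that("reducing the rapid delayed rectifier prolongs the AP", {
  apd <- function(g) compute_biomarkers(simulate_ap(g))[["APD90"]]
  base <- apd(conductance_set())
  expect_gt(apd(conductance_set(gKr = 0.5)), base)
  # repolarization reserve: APD90 non-increasing in gK1 as well
  expect_gt(apd(conductance_set(gK1 = 0.5)), base)
  expect_lt(apd(conductance_set(gK1 = 1.5)), base)
})

test_that("repeated pacing converges towards a limit cycle", {
  p <- pacing_protocol(n_beats = 12, ss_tol = 0)
  tr <- simulate_ap(conductance_set(gKr = 0.8, pCa = 1.1), p)
  deltas <- attr(tr, "beat_deltas")
  expect_length(deltas, 12)
  # per-beat state change decreases (allow small non-monotone wiggle early)
  expect_lt(deltas[12], deltas[2])
  expect_lt(deltas[12], 1e-3)
})

test_that("integrate_beat advances exactly one cycle and matches simulate_ap", {
  p <- fast_protocol(1)
  st <- baseline_state()
  res <- integrate_beat(st, conductance_set(), p)
  expect_equal(range(res$trace$times), c(0, p$cycle_length))
  one <- simulate_ap(conductance_set(), p, state = st)
  p1 <- pacing_protocol(n_beats = 1)
  expect_equal(integrate_beat(st, conductance_set(), p1)$trace$vm,
               simulate_ap(conductance_set(), p1, state = st)$vm)
})

test_that("batch simulation preserves order and isolates failures", {
  p <- fast_protocol()
  gl <- list(conductance_set(), conductance_set(gKr = 0.7),
             conductance_set(gNa = 1.3))
  out <- batch_simulate(gl, p)
  expect_length(out, 3)
  for (i in seq_along(gl))
    expect_equal(out[[i]]$vm, simulate_ap(gl[[i]], p)$vm)
  # permuted input gives permuted output
  out2 <- batch_simulate(gl[c(3, 1, 2)], p)
  expect_equal(out2[[1]]$vm, out[[3]]$vm)
  expect_error(batch_simulate(list(), p), "empty")
})

test_that("random conductance sets within [0.5, 1.5] simulate to finite traces", {
  set.seed(4)
  p <- fast_protocol()
  for (k in 1:10) {
    g <- as_conductance_set(runif(9, 0.5, 1.5))
    tr <- simulate_ap(g, p)
    expect_true(all(is.finite(tr$vm)))
    expect_equal(length(tr$vm), p$cycle_length / p$dt_sample + 1)
  }
})

test_that("halving the solver step changes biomarkers by under 2 percent", {
  b1 <- compute_biomarkers(simulate_ap(conductance_set(),
                                       pacing_protocol(n_beats = 5)))
  b2 <- compute_biomarkers(simulate_ap(conductance_set(),
                                       pacing_protocol(n_beats = 5,
                                                       dt_solver = 0.005)))
  expect_lt(max(abs(b1 - b2) / abs(b1)), 0.02)
})
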