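test_that("biomarkers of a piecewise-linear AP match the closed form", {
  tr <- polyline_ap()
  b <- compute_biomarkers(tr)
  expect_equal(b[["RMP"]], -85)
  expect_equal(b[["Peak"]], 35)
  # amplitude 120 mV; APDx is the time to Peak - x/100 * 120 on the linear
  # fall with slope -0.4 mV/ms starting at t = 5
  expect_equal(b[["APD90"]], 0.9 * 120 / 0.4, tolerance = 1e-3)
  expect_equal(b[["APD50"]], 0.5 * 120 / 0.4, tolerance = 1e-3)
  expect_equal(b[["APD40"]], 0.4 * 120 / 0.4, tolerance = 1e-3)
  expect_equal(b[["Tri90_40"]], b[["APD90"]] - b[["APD40"]])
})

test_that("biomarker errors distinguish missing upstroke from missing APD", {
  flat <- ap_trace(seq(0, 1000, 0.5), rep(-85, 2001))
  expect_error(compute_biomarkers(flat), "no action potential")
  t <- seq(0, 1000, 0.5)
  v <- ifelse(t < 5, -85, 35)          # depolarizes but never repolarizes
  expect_error(compute_biomarkers(ap_trace(t, v)), "never reached")
})

test_that("baseline simulator biomarkers fall within the experimental ranges", {
  b <- compute_biomarkers(baseline_trace())
  expect_true(within_ranges(b, biomarker_ranges()))
  # closed intervals: a biomarker exactly at a bound is inside
  b2 <- b
  b2[["RMP"]] <- -95
  expect_true(within_ranges(b2, biomarker_ranges()))
  b2[["RMP"]] <- -95.01
  expect_false(within_ranges(b2, biomarker_ranges()))
})

test_that("EAD detection flags secondary depolarizations", {
  expect_false(detect_ead(polyline_ap()))              # monotone repolarization
  base <- plateau_ap()
  expect_false(detect_ead(base))
  # 5 mV hump at t = 400 ms: plateau there is about -45 ... -10 mV region
  expect_true(detect_ead(with_hump(base, at = 400, height = 5)))
  # sub-threshold hump (< 1 mV) is ignored
  expect_false(detect_ead(with_hump(base, at = 400, height = 0.5)))
  # hump peaking below the voltage gate is ignored
  expect_false(detect_ead(with_hump(base, at = 510, height = 5)))
})

test_that("EAD detection is robust to sub-threshold noise after smoothing", {
  base <- plateau_ap()
  ead <- with_hump(base, at = 400, height = 5)
  set.seed(2)
  for (k in 1:5) {
    noise <- runif(length(base$vm), -0.12, 0.12)   # amplitude < delta/4
    expect_false(detect_ead(ap_trace(base$times, base$vm + noise)))
    expect_true(detect_ead(ap_trace(ead$times, ead$vm + noise)))
  }
})

test_that("time translation shifts no duration biomarker", {
  tr <- polyline_ap()
  b0 <- compute_biomarkers(tr)
  sh <- ap_trace(tr$times + 40, tr$vm)
  b1 <- compute_biomarkers(sh)
  for (nm in c("dVmMax", "Peak", "APD40", "APD50", "APD90", "Tri90_40"))
    expect_equal(b1[[nm]], b0[[nm]], tolerance = 1e-9)
})

test_that("abnormality check is a disjunction over the last two beats", {
  normal <- plateau_ap()
  ead <- with_hump(normal, at = 400, height = 5)
  expect_false(detect_abnormality(list(normal, normal)))
  expect_true(detect_abnormality(list(normal, ead)))
  expect_true(detect_abnormality(list(ead, normal)))
  # an unrepolarized beat is abnormal even without an EAD deflection
  t <- seq(0, 1000, 0.5)
  v <- -85 + 60 * pmin(t / 5, 1)
  expect_true(detect_abnormality(list(ap_trace(t, v))))
})

test_that("biomarkers are stable under sampling-grid refinement", {
  b1 <- compute_biomarkers(simulate_ap(conductance_set(),
                                       pacing_protocol(dt_sample = 0.02)))
  b2 <- compute_biomarkers(simulate_ap(conductance_set(),
                                       pacing_protocol(dt_sample = 0.01)))
  expect_lt(max(abs(b1 - b2) / abs(b1)), 0.01)
})
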