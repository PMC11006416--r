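test_that("stimulus blanking replaces only the artifact window", {
  t <- seq(0, 1000, 0.1)
  v <- rep(-85, length(t))
  v[t >= 0.4 & t <= 0.6] <- -45                 # +40 mV artifact spike
  v[t >= 5 & t <= 300] <- 0
  beat <- ap_trace(t, v)
  blanked <- blank_stimulus(beat)
  expect_true(all(blanked$vm[t <= 1.75] == v[length(v)]))
  expect_identical(blanked$vm[t > 1.75], v[t > 1.75])
  # idempotence on an already-flat artifact window
  expect_identical(blank_stimulus(blanked)$vm, blanked$vm)
})

test_that("the low-pass filter has unit DC gain and the designed roll-off", {
  t <- seq(0, 100, 0.01)                        # already at 100 kHz
  const <- ap_trace(t, rep(-80, length(t)))
  expect_lt(max(abs(filter_beat(const)$vm + 80)), 1e-8)
  # zero-phase second-order Butterworth: amplitude response |H(f)|^2
  gain_at <- function(freq_khz) {
    v <- sin(2 * pi * freq_khz * t)
    f <- filter_beat(ap_trace(t, v))
    core <- f$times > 20 & f$times < 80         # avoid edge transients
    sqrt(2) * sqrt(mean(f$vm[core]^2))          # RMS amplitude estimate
  }
  # transfer function of the designed digital filter, squared for the
  # forward-backward pass
  bf <- signal::butter(2, 2.5 / 50, type = "low")
  h2 <- function(freq_khz) {
    z <- exp(-1i * 2 * pi * freq_khz / 100 * (0:2))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2
  }
  expect_equal(gain_at(0.1), h2(0.1), tolerance = 0.01)
  expect_gt(gain_at(0.1), 0.99)
  expect_equal(gain_at(10), h2(10), tolerance = 0.05 * h2(10))
  # a single pass of the analog prototype attenuates by ~ -24 dB at 4x the
  # cutoff; the forward-backward pass squares the response (~ -48 dB)
  expect_equal(sqrt(h2(10)), 1 / sqrt(1 + (10 / 2.5)^4), tolerance = 0.2)
  expect_lt(gain_at(10), 10^(-40 / 20))
})

test_that("averaging ten identical beats is the identity with zero spread", {
  rec <- synthesize_recording(noise_sd = 0, jitter_sd = 0, seed = 2,
                              protocol = fast_protocol())
  out <- preprocess_recording(rec)
  expect_equal(out$qc$flagged_pre + out$qc$flagged_post, 0)
  expect_lt(max(out$qc$sd), 1e-9)
})

test_that("averaging reduces independent noise by about sqrt(n)", {
  t <- seq(0, 1000, 0.1)
  clean <- approx(polyline_ap()$times, polyline_ap()$vm, xout = t)$y
  set.seed(5)
  one_noise <- numeric(0); avg_noise <- numeric(0)
  beats <- lapply(1:10, function(i) ap_trace(t, clean + rnorm(length(t), 0, 1)))
  out <- average_and_resample(beats)
  ref <- approx(t, clean, xout = out$trace$times)$y
  resid <- out$trace$vm - ref
  late <- out$trace$times > 20                  # 1 kHz segment, no filtering
  expect_lt(sd(resid[late]), 1 / sqrt(10) * 1.35)
  expect_gt(sd(resid[late]), 1 / sqrt(10) / 1.35)
})

test_that("QC flags fire under excessive pre-peak jitter", {
  t <- seq(0, 1000, 0.1)
  clean <- approx(polyline_ap()$times, polyline_ap()$vm, xout = t)$y
  set.seed(6)
  beats <- lapply(1:10, function(i) {
    shift <- rnorm(1, 0, 1.5)                   # large alignment jitter
    ap_trace(t, approx(t + shift, clean, xout = t, rule = 2)$y)
  })
  out <- average_and_resample(beats)
  expect_gt(out$qc$flagged_pre, 0)
})

test_that("the full pipeline recovers a clean AP from a noisy recording", {
  rec <- synthesize_recording(noise_sd = 1, jitter_sd = 0, seed = 3,
                              protocol = fast_protocol())
  out <- preprocess_recording(rec)
  clean <- attr(rec, "clean")
  sel <- out$trace$times > 5
  ref <- approx(clean$times, clean$vm, xout = out$trace$times[sel])$y
  expect_lt(sqrt(mean((out$trace$vm[sel] - ref)^2)), 1)
  # determinism of the synthesizer
  rec2 <- synthesize_recording(noise_sd = 1, jitter_sd = 0, seed = 3,
                               protocol = fast_protocol())
  expect_identical(rec$beats, rec2$beats)
})

test_that("pair exclusion is symmetric and keyed to training ranges", {
  ranges <- biomarker_ranges()
  mid <- structure(sapply(ranges, mean), class = "biomarker_set")
  bad <- mid
  bad[["APD90"]] <- ranges$APD90[2] + 50
  expect_false(qc_exclude_pair(mid, mid, ranges))
  expect_true(qc_exclude_pair(mid, bad, ranges))
  expect_true(qc_exclude_pair(bad, mid, ranges))
})

test_that("raw recordings round-trip through CSV", {
  rec <- synthesize_recording(noise_sd = 0.5, seed = 9,
                              protocol = fast_protocol())
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_recording(rec, path)
  back <- read_raw_recording(path)
  expect_equal(back$times, rec$times)
  expect_equal(back$beats, rec$beats, tolerance = 1e-9, ignore_attr = TRUE)
})
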