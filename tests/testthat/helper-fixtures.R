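# Shared fixtures, built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# fast pacing protocol for unit tests (few beats; limit-cycle convergence
# is exercised separately)
fast_protocol <- function(n_beats = 3) pacing_protocol(n_beats = n_beats)

# baseline last-beat trace
baseline_trace <- function() memo("baseline_trace", {
  simulate_ap(conductance_set(), pacing_protocol())
})

# a small narrow-range dataset for dataset/training mechanics
tiny_dataset <- function() memo("tiny_dataset", {
  ds <- build_training_set(12, ranges = list(c(0.8, 1.2)),
                           protocol = fast_protocol())
  train_val_split(ds, 0.25, seed = 7)
})

# untrained (randomly initialized) emulator weights
tiny_weights <- function() memo("tiny_weights", init_emulator_weights(seed = 11))

# piecewise-linear synthetic action potential with closed-form biomarkers:
# rest at -85 mV, instantaneous rise to +35 mV at t = 5 ms, linear fall
# back to -85 mV at t = 305 ms
polyline_ap <- function(dt = 0.05) {
  t <- seq(0, 1000, by = dt)
  v <- rep(-85, length(t))
  rise <- t >= 5 & t <= 305
  v[rise] <- 35 - (35 - -85) / 300 * (t[rise] - 5)
  v[t < 5] <- -85
  # sharp upstroke across one sample step
  v[abs(t - 5) < dt / 2] <- 35
  ap_trace(t, v)
}

# plateau-shaped AP: slow decline from +35 to -10 mV (phase 2), then a fast
# phase-3 fall; hump injections on the plateau model EAD deflections
plateau_ap <- function(dt = 0.05) {
  t <- seq(0, 1000, by = dt)
  v <- rep(-85, length(t))
  v[t >= 5 & t < 450] <- 35 - 0.1 * (t[t >= 5 & t < 450] - 5)
  v[t >= 450 & t < 550] <- -10 - 0.75 * (t[t >= 450 & t < 550] - 450)
  ap_trace(t, v)
}

# add a secondary depolarizing hump to a repolarizing phase
with_hump <- function(trace, at = 400, sigma = 10, height = 5) {
  v <- trace$vm + height * exp(-(trace$times - at)^2 / (2 * sigma^2))
  ap_trace(trace$times, v)
}
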