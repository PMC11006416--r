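#' Raw multi-beat recording
#'
#' Container for microelectrode-style raw data: the last consecutive beats
#' of a measurement, all sampled on one uniform raw grid.
#'
#' @param times uniform sample times in ms (one beat window).
#' @param beats numeric matrix, one row per beat.
#' @return A list of class `raw_recording`.
#' @export
raw_recording <- function(times, beats) {
  beats <- as.matrix(beats)
  if (is.null(dim(beats)) || nrow(beats) < 1) stop("at least one beat required")
  if (ncol(beats) != length(times)) stop("beats and times lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), beats = beats),
            class = "raw_recording")
}

#' @rdname raw_recording
#' @param path CSV path with columns `time_ms, beat_1, ..., beat_k`.
#' @export
read_raw_recording <- function(path) {
  df <- utils::read.csv(path)
  raw_recording(df[[1]], t(as.matrix(df[, -1, drop = FALSE])))
}

#' @rdname raw_recording
#' @param x a `raw_recording`.
#' @export
write_raw_recording <- function(x, path) {
  df <- data.frame(time_ms = x$times, t(x$beats))
  names(df)[-1] <- paste0("beat_", seq_len(nrow(x$beats)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Blank the stimulus artifact of a beat
#'
#' Defines the resting membrane potential as the potential at the sample
#' closest to the end of the beat and overwrites the artifact window
#' `t` in `[0, 1.75]` ms with that value.  Samples outside the window are
#' never altered.
#'
#' @param beat an [ap_trace()].
#' @param window artifact window end in ms (default 1.75).
#' @return The blanked `ap_trace`.
#' @export
blank_stimulus <- function(beat, window = 1.75) {
  rmp <- beat$vm[length(beat$vm)]
  sel <- beat$times >= 0 & beat$times <= window
  beat$vm[sel] <- rmp
  beat
}

#' Low-pass filter a beat
#'
#' Linearly resamples the beat to 100 kHz and applies a second-order
#' low-pass Butterworth filter with 2.5 kHz cutoff.  The filter is run in
#' zero-phase (forward-backward) mode so the depolarization time is not
#' shifted.
#'
#' @param beat an [ap_trace()] (blanked).
#' @param fs resampling rate in kHz (default 100).
#' @param cutoff cutoff frequency in kHz (default 2.5).
#' @return The filtered `ap_trace` on the 100 kHz grid.
#' @export
filter_beat <- function(beat, fs = 100, cutoff = 2.5) {
  dt <- 1 / fs
  grid <- seq(min(beat$times), max(beat$times), by = dt)
  pad <- 400L                       # reflection padding against edge transients
  if (length(grid) < pad + 2L)
    stop("beat too short for the filter warm-up")
  v <- stats::approx(beat$times, beat$vm, xout = grid)$y
  v0 <- v - v[1]                    # anchor the baseline to suppress the
  n <- length(v0)                   # zero-state start-up transient
  vp <- c(rev(v0[2:(pad + 1)]), v0, rev(v0[(n - pad):(n - 1)]))
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  vf <- signal::filtfilt(bf, vp)[(pad + 1):(pad + n)] + v[1]
  ap_trace(grid, vf, cycle_length = beat$cycle_length, beat = beat$beat)
}

#' Average filtered beats and resample non-uniformly
#'
#' Computes the pointwise mean across beats and resamples the averaged AP
#' at 100 kHz for `t` in `[0, 15)` ms (depolarization) and 1 kHz for
#' `t` in `[15, 1000]` ms (repolarization).  The QC report contains the
#' across-beat standard deviation over time, flagged where it exceeds
#' 7 mV before the AP peak or 2 mV after it.
#'
#' @param beats list of filtered `ap_trace`s on one common grid.
#' @param sd_pre,sd_post QC thresholds in mV.
#' @return A list: `trace` (averaged, resampled `ap_trace`) and `qc`
#'   (list with `sd` trace, `flagged_pre`, `flagged_post` counts).
#' @export
average_and_resample <- function(beats, sd_pre = 7, sd_post = 2) {
  stopifnot(length(beats) >= 1)
  times <- beats[[1]]$times
  for (b in beats)
    if (!isTRUE(all.equal(b$times, times))) stop("beat grids differ")
  M <- do.call(rbind, lapply(beats, `[[`, "vm"))
  avg <- colMeans(M)
  sdv <- if (nrow(M) > 1) apply(M, 2, stats::sd) else rep(0, ncol(M))
  ipeak <- which.max(avg)
  flag_pre <- sum(sdv[seq_len(ipeak)] > sd_pre)
  flag_post <- sum(sdv[-seq_len(ipeak)] > sd_post)
  grid <- c(seq(0, 15 - 0.01, by = 0.01), seq(15, 1000, by = 1))
  grid <- grid[grid >= min(times) & grid <= max(times)]
  vm <- stats::approx(times, avg, xout = grid)$y
  list(trace = ap_trace(grid, vm, cycle_length = beats[[1]]$cycle_length),
       qc = list(times = times, sd = sdv, flagged_pre = flag_pre,
                 flagged_post = flag_post,
                 thresholds = c(pre = sd_pre, post = sd_post)))
}

#' Full preprocessing pipeline for a raw recording
#'
#' Blank, filter, and average all beats of a recording.
#'
#' @param recording a [raw_recording()].
#' @param ... passed to [average_and_resample()].
#' @return As [average_and_resample()].
#' @export
preprocess_recording <- function(recording, ...) {
  stopifnot(inherits(recording, "raw_recording"))
  beats <- lapply(seq_len(nrow(recording$beats)), function(i)
    filter_beat(blank_stimulus(ap_trace(recording$times,
                                        recording$beats[i, ]))))
  average_and_resample(beats, ...)
}

#' Exclude a control/drug pair outside the training biomarker ranges
#'
#' A pair of averaged APs is excluded when any biomarker of either AP
#' falls outside the ranges observed in the training corpus.
#'
#' @param control_bm,drug_bm `biomarker_set`s of the averaged control and
#'   drugged APs.
#' @param training_ranges named list of `c(min, max)` per biomarker, as
#'   returned by [dataset_biomarker_ranges()].
#' @return `TRUE` if the pair is to be excluded.
#' @export
qc_exclude_pair <- function(control_bm, drug_bm, training_ranges) {
  !within_ranges(control_bm, training_ranges) ||
    !within_ranges(drug_bm, training_ranges)
}

#' Synthesize a raw recording from the simulator
#'
#' Generates an experimental-style raw recording: the simulated (optionally
#' drugged) steady-state AP repeated over `n_beats`, with a stimulus
#' artifact spike in `[0, 1.5]` ms, independent Gaussian sample noise, and
#' per-beat alignment jitter.
#'
#' @param conductances control [conductance_set()].
#' @param drug optional [synthetic_drug()] applied before simulation.
#' @param n_beats number of recorded beats (default 10).
#' @param noise_sd Gaussian noise standard deviation in mV.
#' @param jitter_sd per-beat alignment jitter standard deviation in ms.
#' @param artifact_mV amplitude of the stimulus artifact spike.
#' @param raw_dt raw sampling step in ms.
#' @param protocol a [pacing_protocol()].
#' @param seed RNG seed.
#' @return A [raw_recording()]; the clean simulated trace is attached as
#'   attribute `clean`.
#' @export
synthesize_recording <- function(conductances = conductance_set(),
                                 drug = NULL, n_beats = 10, noise_sd = 1,
                                 jitter_sd = 0.1, artifact_mV = 40,
                                 raw_dt = 0.1,
                                 protocol = pacing_protocol(), seed = 1L) {
  g <- as_conductance_set(conductances)
  if (!is.null(drug)) g <- apply_drug(g, drug)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  clean <- simulate_ap(g, protocol)
  times <- seq(0, protocol$cycle_length, by = raw_dt)
  base <- stats::approx(clean$times, clean$vm, xout = times)$y
  beats <- matrix(NA_real_, n_beats, length(times))
  for (i in seq_len(n_beats)) {
    jit <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
    v <- stats::approx(times + jit, base, xout = times, rule = 2)$y
    art <- times >= 0 & times <= 1.5
    v[art] <- v[art] + artifact_mV * exp(-times[art] / 0.4)
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    beats[i, ] <- v
  }
  out <- raw_recording(times, beats)
  attr(out, "clean") <- clean
  out
}
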