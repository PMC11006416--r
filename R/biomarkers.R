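#' Compute the seven scalar AP biomarkers
#'
#' Computes resting membrane potential (`RMP`, mV), maximum upstroke
#' velocity (`dVmMax`, mV/ms), peak potential (`Peak`, mV), action-potential
#' durations at 40/50/90 % repolarization (`APD40`, `APD50`, `APD90`, ms)
#' and triangulation (`Tri90_40 = APD90 - APD40`, ms).
#'
#' Conventions: `RMP` is the potential at stimulus onset (the last sample
#' with `t <= 0`, i.e. the held pre-stimulus value); `Peak` is the maximum
#' of the trace; `dVmMax` the maximum finite-difference derivative; the
#' activation time is the time of `dVmMax`; `APDx` is the time from
#' activation until the potential first falls below
#' `Peak - x/100 * (Peak - RMP)`, with the crossing linearly interpolated
#' between samples.
#'
#' @param trace an [ap_trace()] covering at least `[0, 1000]` ms and
#'   containing a stimulus-evoked upstroke.
#' @param upstroke_min minimum `dVmMax` (mV/ms) for the trace to count as an
#'   action potential.
#' @return Named numeric vector of class `biomarker_set` with elements
#'   `RMP`, `dVmMax`, `Peak`, `APD40`, `APD50`, `APD90`, `Tri90_40`.
#' @export
compute_biomarkers <- function(trace, upstroke_min = 10) {
  t <- trace$times; v <- trace$vm
  i0 <- which(t <= 0)
  rmp <- if (length(i0)) v[max(i0)] else v[1L]
  dv <- diff(v) / diff(t)
  imax <- which.max(dv)
  dvmax <- dv[imax]
  # refine the peak slope with a parabola through the three neighbouring
  # finite-difference values, so the estimate is stable under resampling
  if (imax > 1L && imax < length(dv)) {
    tm <- (t[-1] + t[-length(t)]) / 2
    x1 <- tm[imax - 1L]; x2 <- tm[imax]; x3 <- tm[imax + 1L]
    y1 <- dv[imax - 1L]; y2 <- dv[imax]; y3 <- dv[imax + 1L]
    a <- ((y3 - y2) / (x3 - x2) - (y2 - y1) / (x2 - x1)) / (x3 - x1)
    if (is.finite(a) && a < 0) {
      bq <- (y2 - y1) / (x2 - x1) - a * (x1 + x2)
      xv <- -bq / (2 * a)
      if (xv >= x1 && xv <= x3) {
        cq <- y2 - a * x2^2 - bq * x2
        dvmax <- a * xv^2 + bq * xv + cq
      }
    }
  }
  if (!is.finite(dvmax) || dvmax < upstroke_min)
    stop("no action potential: maximum upstroke velocity ",
         format(dvmax, digits = 3), " mV/ms below ", upstroke_min,
         call. = FALSE)
  t_act <- t[imax + 1L]           # time at which the steepest rise completes
  ipeak <- which.max(v)
  peak <- v[ipeak]
  apd <- function(x) {
    thr <- peak - x / 100 * (peak - rmp)
    after <- which(t > t[ipeak])
    below <- after[v[after] < thr]
    if (!length(below))
      stop(sprintf("APD%d undefined: %d%% repolarization level never reached",
                   x, x), call. = FALSE)
    i <- below[1L]
    # linear interpolation of the downward crossing between i-1 and i
    tcross <- t[i - 1L] + (thr - v[i - 1L]) * (t[i] - t[i - 1L]) / (v[i] - v[i - 1L])
    tcross - t_act
  }
  b <- c(RMP = rmp, dVmMax = dvmax, Peak = peak,
         APD40 = apd(40), APD50 = apd(50), APD90 = apd(90))
  b <- c(b, Tri90_40 = unname(b["APD90"] - b["APD40"]))
  structure(b, class = "biomarker_set")
}

#' Experimental biomarker ranges for population calibration
#'
#' The seven biomarker ranges measured at 37 degrees C in small human right
#' ventricular trabeculae and papillary preparations paced at 1000 ms cycle
#' length, used to calibrate the synthetic cardiomyocyte population.
#'
#' @return A named list; each element is `c(min, max)`.
#' @export
biomarker_ranges <- function() {
  list(RMP = c(-95, -80), dVmMax = c(100, 1000), Peak = c(10, 55),
       APD40 = c(85, 320), APD50 = c(110, 350), APD90 = c(180, 440),
       Tri90_40 = c(50, 150))
}

#' Test whether biomarkers fall within ranges
#'
#' @param b a `biomarker_set` from [compute_biomarkers()].
#' @param ranges a named list of `c(min, max)` bounds (closed intervals),
#'   default [biomarker_ranges()].
#' @return `TRUE` iff every biomarker named in `ranges` lies inside its
#'   closed interval.
#' @export
within_ranges <- function(b, ranges = biomarker_ranges()) {
  stopifnot(all(vapply(ranges, function(r) r[1] < r[2], logical(1))))
  all(vapply(names(ranges), function(nm) {
    x <- unname(b[[nm]])
    x >= ranges[[nm]][1] && x <= ranges[[nm]][2]
  }, logical(1)))
}

#' Detect early afterdepolarizations
#'
#' Classifies a trace as EAD-positive when, after the AP peak plus a guard
#' interval, the (smoothed) potential has a local minimum followed by a
#' later local maximum at least `delta_ead` above it, with that maximum
#' above `v_gate`.  This captures the conventional definition of an EAD as
#' a depolarizing deflection during phase 2/3 repolarization.
#'
#' @param trace an [ap_trace()].
#' @param delta_ead minimum secondary-rise amplitude in mV.
#' @param v_gate minimum potential (mV) the secondary maximum must exceed.
#' @param guard_ms interval after the AP peak that is ignored.  The default
#'   of 100 ms covers the model's physiological phase-1 notch-and-dome so
#'   that only deflections during established repolarization are flagged.
#' @param smooth_n width (samples) of the moving-average smoothing applied
#'   before extremum detection.
#' @return logical flag.
#' @export
detect_ead <- function(trace, delta_ead = 1, v_gate = -40, guard_ms = 100,
                       smooth_n = 5) {
  t <- trace$times; v <- trace$vm
  if (smooth_n > 1) {
    k <- rep(1 / smooth_n, smooth_n)
    vs <- stats::filter(v, k, sides = 2)
    pad <- which(is.na(vs))
    vs[pad] <- v[pad]
    v <- as.numeric(vs)
  }
  ipeak <- which.max(v)
  sel <- which(t >= t[ipeak] + guard_ms)
  if (length(sel) < 3L) return(FALSE)
  v <- v[sel]
  run_min <- cummin(v)
  d <- diff(v)
  # indices of strict local maxima of the smoothed tail
  imax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  any(v[imax] - run_min[pmax(imax - 1L, 1L)] >= delta_ead & v[imax] > v_gate)
}

#' Detect repolarization abnormality over the last beats
#'
#' A preparation is abnormal when either of its last two beats shows an
#' early afterdepolarization or fails the repolarization criterion of
#' [is_unrepolarized()].
#'
#' @param last_traces list of the last one or two beat traces.
#' @param ... passed to [detect_ead()].
#' @return logical flag.
#' @export
detect_abnormality <- function(last_traces, ...) {
  if (inherits(last_traces, "ap_trace")) last_traces <- list(last_traces)
  any(vapply(last_traces, function(tr) {
    is_unrepolarized(tr) || detect_ead(tr, ...)
  }, logical(1)))
}

#' Read and write biomarker sets as CSV
#'
#' @param x a `biomarker_set` or list of them.
#' @param path file path.
#' @return `read_biomarkers` returns a list of `biomarker_set`s.
#' @export
write_biomarkers <- function(x, path) {
  if (inherits(x, "biomarker_set")) x <- list(x)
  m <- do.call(rbind, lapply(x, unclass))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biomarkers
#' @export
read_biomarkers <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    structure(unlist(df[i, ]), class = "biomarker_set"))
}
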