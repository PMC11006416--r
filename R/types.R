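#' Conductance scale factors
#'
#' A `conductance_set` holds the nine dimensionless scale factors that
#' multiply the model's baseline current magnitudes: fast sodium (`gNa`),
#' late sodium (`gNaL`), L-type calcium permeability (`pCa`), transient
#' outward (`gto`), rapid (`gKr`) and slow (`gKs`) delayed rectifier, inward
#' rectifier (`gK1`), sodium-calcium exchange (`gNCX`) and sodium-potassium
#' pump (`pNaK`).  A factor of 1 is the baseline; 0 is full block.  All
#' workflows in this package operate on factors in `[0, 2]`.
#'
#' @param gNa,gNaL,pCa,gto,gKr,gKs,gK1,gNCX,pNaK dimensionless scale
#'   factors, each in `[0, 2]`.
#' @return A named numeric vector of class `conductance_set`, in the fixed
#'   order `gNa, gNaL, pCa, gto, gKr, gKs, gK1, gNCX, pNaK`.
#' @export
#' @examples
#' conductance_set(gKr = 0.5)
conductance_set <- function(gNa = 1, gNaL = 1, pCa = 1, gto = 1, gKr = 1,
                            gKs = 1, gK1 = 1, gNCX = 1, pNaK = 1) {
  g <- c(gNa = gNa, gNaL = gNaL, pCa = pCa, gto = gto, gKr = gKr,
         gKs = gKs, gK1 = gK1, gNCX = gNCX, pNaK = pNaK)
  validate_conductances(g)
  structure(g, class = "conductance_set")
}

#' @rdname conductance_set
#' @param x numeric vector of length 9 (optionally named) to coerce.
#' @export
as_conductance_set <- function(x) {
  x <- unclass(x)
  if (length(x) != 9L) stop("a conductance set has exactly 9 entries")
  nm <- conductance_names()
  if (!is.null(names(x))) {
    if (!setequal(names(x), nm)) stop("unknown conductance names: ",
                                      paste(setdiff(names(x), nm), collapse = ", "))
    x <- x[nm]
  } else {
    names(x) <- nm
  }
  validate_conductances(x)
  structure(as.numeric(`names<-`(x, nm)), names = nm, class = "conductance_set")
}

#' @rdname conductance_set
#' @export
conductance_names <- function() {
  c("gNa", "gNaL", "pCa", "gto", "gKr", "gKs", "gK1", "gNCX", "pNaK")
}

validate_conductances <- function(g) {
  if (any(!is.finite(g))) stop("conductance scale factors must be finite")
  if (any(g < 0)) stop("conductance scale factors must be >= 0")
  if (any(g > 2)) stop("conductance scale factors must be <= 2")
  invisible(g)
}

#' Pacing protocol
#'
#' Describes the stimulation protocol: pacing cycle length, a rectangular
#' transmembrane current pulse, the number of conditioning beats, and the
#' solver/sampling steps.  The default protocol paces at 1000 ms cycle
#' length with a 1 ms stimulus and runs up to 200 beats with an early stop
#' once the per-beat relative state change falls below `ss_tol`, which
#' approximates the model's limit cycle.
#'
#' @param cycle_length pacing cycle length in ms.
#' @param stim_duration stimulus duration in ms (must be < `cycle_length`).
#' @param stim_amplitude stimulus current density magnitude (uA/uF).
#' @param n_beats maximum number of paced beats.
#' @param dt_solver solver time step in ms.
#' @param dt_sample sampling time step in ms (integer multiple of
#'   `dt_solver`).
#' @param ss_tol relative per-beat state-change tolerance for the early
#'   stop; set to 0 to always run all `n_beats`.
#' @return A list of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cycle_length = 1000, stim_duration = 1,
                            stim_amplitude = 80, n_beats = 200,
                            dt_solver = 0.01, dt_sample = 0.05,
                            ss_tol = 1e-4) {
  stopifnot(cycle_length > 0, stim_duration > 0, stim_duration < cycle_length,
            n_beats >= 1, dt_solver > 0, dt_sample >= dt_solver, ss_tol >= 0)
  k <- dt_sample / dt_solver
  if (abs(k - round(k)) > 1e-8)
    stop("dt_sample must be an integer multiple of dt_solver")
  structure(list(cycle_length = cycle_length, stim_duration = stim_duration,
                 stim_amplitude = stim_amplitude, n_beats = as.integer(n_beats),
                 dt_solver = dt_solver, dt_sample = dt_sample,
                 ss_tol = ss_tol),
            class = "pacing_protocol")
}

#' Action-potential trace
#'
#' The universal exchange object of the package: a sampled transmembrane
#' potential over (at least) one pacing cycle.
#'
#' @param times sample times in ms, strictly increasing.
#' @param vm transmembrane potential in mV, same length as `times`.
#' @param cycle_length pacing cycle length metadata in ms.
#' @param beat index of the beat within the pacing series, if known.
#' @return A list of class `ap_trace` with elements `times`, `vm`,
#'   `cycle_length` and `beat`.
#' @export
ap_trace <- function(times, vm, cycle_length = 1000, beat = NA_integer_) {
  times <- as.numeric(times); vm <- as.numeric(vm)
  if (length(times) != length(vm)) stop("times and vm must have equal length")
  if (length(times) < 2L) stop("a trace needs at least 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(vm))) stop("vm must be finite")
  structure(list(times = times, vm = vm, cycle_length = cycle_length,
                 beat = beat),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d samples, t in [%g, %g] ms, vm in [%.1f, %.1f] mV\n",
              length(x$times), min(x$times), max(x$times),
              min(x$vm), max(x$vm)))
  invisible(x)
}

#' @export
print.conductance_set <- function(x, ...) {
  cat("<conductance_set>\n")
  print(unclass(x), ...)
  invisible(x)
}

# interpolate a trace at arbitrary times (linear, no extrapolation)
trace_at <- function(trace, t) {
  stats::approx(trace$times, trace$vm, xout = t, rule = 1)$y
}

#' Read and write conductance sets as CSV
#'
#' The CSV has a header row naming the nine parameters in the fixed order
#' `gNa,gNaL,pCa,gto,gKr,gKs,gK1,gNCX,pNaK` and one row per set.
#'
#' @param path file path.
#' @param x a `conductance_set` or list of them.
#' @return `read_conductances` returns a list of `conductance_set`s;
#'   `write_conductances` returns `path` invisibly.
#' @export
read_conductances <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!setequal(names(df), conductance_names()))
    stop("CSV must have exactly the nine conductance columns")
  lapply(seq_len(nrow(df)), function(i)
    as_conductance_set(unlist(df[i, conductance_names()])))
}

#' @rdname read_conductances
#' @export
write_conductances <- function(x, path) {
  if (inherits(x, "conductance_set")) x <- list(x)
  m <- do.call(rbind, lapply(x, function(g) unclass(as_conductance_set(g))))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Read and write single AP traces as two-column CSV
#'
#' @param path file path.
#' @param trace an `ap_trace`.
#' @param ... passed to [ap_trace()] (metadata).
#' @return `read_ap_trace` returns an `ap_trace`; `write_ap_trace` returns
#'   `path` invisibly.
#' @export
read_ap_trace <- function(path, ...) {
  df <- utils::read.csv(path)
  ap_trace(df[[1]], df[[2]], ...)
}

#' @rdname read_ap_trace
#' @export
write_ap_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$times, vm_mV = trace$vm),
                   path, row.names = FALSE)
  invisible(path)
}
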