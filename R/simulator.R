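#' @useDynLib apemu, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Baseline resting state of the reduced model, obtained by pacing the
# baseline parameter set to its limit cycle and reading the state at the end
# of a cycle.  Order: V, m, h, j, d, f, x, xs, r, q, hL, Cai.
.state_names <- c("V", "m", "h", "j", "d", "f", "x", "xs", "r", "q", "hL", "Cai")

#' Baseline initial state of the reduced ionic model
#'
#' The model state at the end of a baseline-paced cycle (all scale factors
#' 1, default protocol), used as the initial condition for every simulation
#' so that paced runs converge to the limit cycle within a few beats.
#'
#' @return Named numeric vector of the 12 state variables.
#' @export
baseline_state <- function() {
  s <- c(V = -87.9839733436987, m = 0.000938138043674305, h = 0.992252324518782,
         j = 0.994840714517648, d = 0.00223022977482821, f = 0.999989660038191,
         x = 0.0196631954205163, xs = 0.00132113364020045, r = 1.52709065803554e-08,
         q = 0.999998755492052, hL = 0.368390423966945, Cai = 0.000154532285225919)
  s[.state_names]
}

#' Simulate a paced action potential
#'
#' Paces the reduced ventricular cardiomyocyte model from the baseline
#' initial state with the given conductance scale factors and returns the
#' last beat's action potential sampled on `[0, cycle_length]` at
#' `dt_sample`.  The state is carried across beats, so with enough beats the
#' returned trace approximates the model's limit cycle.
#'
#' @param conductances a [conductance_set()] (or coercible vector).
#' @param protocol a [pacing_protocol()].
#' @param state optional initial state (defaults to [baseline_state()]).
#' @return An `ap_trace` with attributes `state` (final model state),
#'   `beats_run` and `beat_deltas` (per-beat relative state change).
#' @export
#' @examples
#' \donttest{
#' ap <- simulate_ap(conductance_set(), pacing_protocol(n_beats = 5))
#' }
simulate_ap <- function(conductances, protocol = pacing_protocol(),
                        state = baseline_state()) {
  g <- as_conductance_set(conductances)
  stopifnot(inherits(protocol, "pacing_protocol"))
  if (any(!is.finite(state))) stop("initial state must be finite")
  res <- .cpp_run_beats(as.numeric(state), as.numeric(g),
                        protocol$cycle_length, protocol$stim_duration,
                        protocol$stim_amplitude, protocol$n_beats,
                        protocol$dt_solver, protocol$dt_sample,
                        protocol$ss_tol, protocol$ss_tol > 0)
  if (!isTRUE(res$ok))
    stop(sprintf("integration failure: %s at t = %.4f ms (beat %d)",
                 res$message, res$fail_time, res$fail_beat))
  tr <- ap_trace(res$times, res$vm, cycle_length = protocol$cycle_length,
                 beat = res$beats_run)
  attr(tr, "state") <- stats::setNames(res$state, .state_names)
  attr(tr, "beats_run") <- res$beats_run
  attr(tr, "beat_deltas") <- res$deltas
  tr
}

#' Advance the model by exactly one paced beat
#'
#' @inheritParams simulate_ap
#' @param state the current model state (named numeric vector of the 12
#'   state variables).
#' @return A list with `state` (the state after one cycle) and `trace` (the
#'   beat's sampled `ap_trace`).
#' @export
integrate_beat <- function(state, conductances, protocol = pacing_protocol()) {
  g <- as_conductance_set(conductances)
  stopifnot(inherits(protocol, "pacing_protocol"))
  if (any(!is.finite(state))) stop("state must be finite")
  res <- .cpp_run_beats(as.numeric(state), as.numeric(g),
                        protocol$cycle_length, protocol$stim_duration,
                        protocol$stim_amplitude, 1L,
                        protocol$dt_solver, protocol$dt_sample, 0, FALSE)
  if (!isTRUE(res$ok))
    stop(sprintf("integration failure: %s at t = %.4f ms (beat %d)",
                 res$message, res$fail_time, res$fail_beat))
  list(state = stats::setNames(res$state, .state_names),
       trace = ap_trace(res$times, res$vm,
                        cycle_length = protocol$cycle_length, beat = 1L))
}

#' Simulate a list of conductance sets
#'
#' Order-preserving batch wrapper around [simulate_ap()].  Per-item
#' integration failures are collected rather than aborting the batch.
#'
#' @param conductance_list list of conductance sets.
#' @param protocol a [pacing_protocol()].
#' @param quiet suppress the per-failure messages.
#' @return A list the same length as `conductance_list`; each element is an
#'   `ap_trace` or `NULL` for a failed item.  Failure messages are attached
#'   as attribute `failures` (named by item index).
#' @export
batch_simulate <- function(conductance_list, protocol = pacing_protocol(),
                           quiet = FALSE) {
  if (length(conductance_list) == 0L) stop("empty conductance list")
  failures <- character()
  out <- vector("list", length(conductance_list))
  for (i in seq_along(conductance_list)) {
    out[[i]] <- tryCatch(simulate_ap(conductance_list[[i]], protocol),
                         error = function(e) {
                           failures[[as.character(i)]] <<- conditionMessage(e)
                           if (!quiet) message("item ", i, ": ", conditionMessage(e))
                           NULL
                         })
  }
  attr(out, "failures") <- failures
  out
}
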