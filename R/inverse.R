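#' Inverse-fitting configuration
#'
#' Settings for the projected-Adam minimization of the time-series fitting
#' objective: data mismatch `1/(2|T|) sum_t (Vm(x, t - t0) - target(t))^2`
#' plus the prior penalty `lambda_x0/2 * ||x - x_prior||^2`, subject to the
#' box constraint `x` in `[-0.5, 0.5]^9` (enforced by projection after
#' every step).  The temporal offset `t0` is optimized jointly with its own
#' (smaller) step size and is unconstrained.
#'
#' @param lambda_x0 prior weight (default 10).
#' @param iterations number of Adam iterations (fixed-count convergence).
#' @param lr Adam step size for the conductance coordinates.
#' @param lr_t0 Adam step size for the time offset (ms scale).
#' @param beta1,beta2 Adam moment decays.
#' @param log_every record the objective every this many iterations.
#' @param seed RNG seed (the fit itself is deterministic; recorded for
#'   provenance).
#' @param precision floating-point precision of the emulator evaluations
#'   during the iterations (the final reported fit is always evaluated in
#'   double).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lambda_x0 = 10, iterations = 10000, lr = 0.01,
                       lr_t0 = 0.02, beta1 = 0.9, beta2 = 0.999,
                       log_every = 25, seed = 1L,
                       precision = c("double", "single")) {
  precision <- match.arg(precision)
  stopifnot(lambda_x0 >= 0, iterations >= 1, lr > 0, lr_t0 > 0)
  structure(as.list(environment()), class = "fit_config")
}

#' Desk-scale fitting configuration
#'
#' Shorter iteration count suited to batched fits of emulated targets on a
#' single CPU.
#'
#' @param iterations,... overrides passed to [fit_config()].
#' @export
desk_fit_config <- function(iterations = 1500, ...) {
  fit_config(iterations = iterations, precision = "single", ...)
}

# core batched fitter: targets is B x Tn on a shared time vector
fit_engine <- function(targets, times, x_init, x_prior, w, cfg) {
  B <- nrow(targets); Tn <- ncol(targets)
  stopifnot(length(times) == Tn, nrow(x_init) == B, nrow(x_prior) == B)
  dom <- w$t_domain
  if (min(times) < dom[1] - 1e-9 || max(times) > dom[2] + 1e-9)
    stop("target times outside the trained domain [", dom[1], ", ", dom[2], "] ms")
  x <- pmin(pmax(x_init, -0.5), 0.5)
  t0 <- rep(0, B)
  mx <- x * 0; vx <- x * 0; mt <- t0 * 0; vt <- t0 * 0
  clamped_warned <- FALSE
  obj_log <- NULL
  for (it in seq_len(cfg$iterations)) {
    tm <- outer(rep(1, B), times) - t0
    if (any(tm < dom[1] | tm > dom[2])) {
      if (!clamped_warned) {
        warning("shifted evaluation times clamped to the trained domain")
        clamped_warned <- TRUE
      }
      tm <- pmin(pmax(tm, dom[1]), dom[2])
    }
    res <- emu_eval(w, x, tm, target = targets,
                    want_x_grad = TRUE, want_t_grad = TRUE,
                    precision = cfg$precision)
    if (!is.finite(res$loss))
      stop("fit diverged (non-finite objective) at iteration ", it)
    prior <- cfg$lambda_x0 / 2 * sum((x - x_prior)^2)
    gx <- res$dX + cfg$lambda_x0 * (x - x_prior)
    gt <- -as.numeric(res$dt)
    # Adam with bias correction, then projection onto the feasible box
    c1 <- 1 - cfg$beta1^it; c2 <- 1 - cfg$beta2^it
    mx <- cfg$beta1 * mx + (1 - cfg$beta1) * gx
    vx <- cfg$beta2 * vx + (1 - cfg$beta2) * gx^2
    x <- x - cfg$lr * (mx / c1) / (sqrt(vx / c2) + 1e-8)
    x <- pmin(pmax(x, -0.5), 0.5)
    mt <- cfg$beta1 * mt + (1 - cfg$beta1) * gt
    vt <- cfg$beta2 * vt + (1 - cfg$beta2) * gt^2
    t0 <- t0 - cfg$lr_t0 * (mt / c1) / (sqrt(vt / c2) + 1e-8)
    if (it %% cfg$log_every == 0 || it == 1 || it == cfg$iterations)
      obj_log <- rbind(obj_log, c(iteration = it,
                                  objective = res$loss + prior))
  }
  tm <- pmin(pmax(outer(rep(1, B), times) - t0, dom[1]), dom[2])
  res <- emu_eval(w, x, tm)
  rmse <- sqrt(rowMeans((res$pred - targets)^2))
  structure(list(x_hat = x, t0 = t0, rmse = rmse,
                 objective = unname(obj_log[nrow(obj_log), 2]),
                 log = as.data.frame(obj_log)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d fit(s), trace RMSE %s mV, objective %.4g\n",
              nrow(x$x_hat), paste(sprintf("%.2f", x$rmse), collapse = "/"),
              x$objective))
  invisible(x)
}

as_target_matrix <- function(target) {
  if (inherits(target, "ap_trace"))
    return(list(vm = matrix(target$vm, 1), times = target$times))
  if (is.list(target)) {
    times <- target[[1]]$times
    for (tr in target)
      if (!isTRUE(all.equal(tr$times, times)))
        stop("batched targets must share one time grid")
    return(list(vm = do.call(rbind, lapply(target, `[[`, "vm")), times = times))
  }
  stop("target must be an ap_trace or a list of ap_traces")
}

#' Fit an action potential with the emulator
#'
#' Estimates normalized conductances (and a temporal offset) for one or
#' several target APs by projected-Adam minimization of the fitting
#' objective (see [fit_config()]).  Multiple targets sharing a time grid
#' are fitted jointly as independent problems in one batch.
#'
#' @param target an [ap_trace()] or list of traces on a common grid.
#' @param x_init initial normalized conductances: length-9 vector or
#'   `B x 9` matrix.
#' @param x_prior prior center, same shape as `x_init`.
#' @param w trained `emulator_weights`.
#' @param cfg a [fit_config()].
#' @return A `fit_result`: `x_hat` (`B x 9` matrix), `t0` (vector, ms),
#'   per-target trace `rmse` (mV), final `objective` and an objective
#'   `log` data frame.
#' @export
fit_ap <- function(target, x_init, x_prior, w, cfg = fit_config()) {
  stopifnot(inherits(w, "emulator_weights"), inherits(cfg, "fit_config"))
  tg <- as_target_matrix(target)
  B <- nrow(tg$vm)
  to_mat <- function(z) {
    m <- if (is.matrix(z)) z else matrix(z, B, 9, byrow = TRUE)
    if (any(m < -0.5 - 1e-12 | m > 0.5 + 1e-12))
      stop("x_init and x_prior must lie in [-0.5, 0.5]")
    m
  }
  fit_engine(tg$vm, tg$times, to_mat(x_init), to_mat(x_prior), w, cfg)
}

#' Estimate control maximum conductances from a control AP
#'
#' Fits the control AP using the reference (baseline) maximum conductances
#' as initial guess and prior: `x_init = x_prior = 0`.
#'
#' @inheritParams fit_ap
#' @export
estimate_control <- function(target, w, cfg = fit_config()) {
  B <- nrow(as_target_matrix(target)$vm)
  fit_ap(target, matrix(0, B, 9), matrix(0, B, 9), w, cfg)
}

#' Estimate drugged maximum conductances from a drugged AP
#'
#' Fits the drugged AP using the conductances estimated from the matching
#' control AP as initial guess and prior: `x_init = x_prior = x_control`.
#'
#' @inheritParams fit_ap
#' @param x_control normalized conductances estimated from the control AP
#'   (vector or `B x 9` matrix).
#' @export
estimate_drug <- function(target, x_control, w, cfg = fit_config()) {
  fit_ap(target, x_control, x_control, w, cfg)
}

#' Pharmacological scaling factors from control and drug estimates
#'
#' Computes the per-target drug effect as the element-wise ratio of the
#' drugged to the control maximum conductances on the physical
#' (denormalized) scale: `s_i = G_drug_i / G_control_i`.
#'
#' @param x_control,x_drug normalized conductance estimates (length 9).
#' @param g_ref reference conductances used for denormalization.
#' @return Named numeric vector of nine ratios, class `scaling_factors`.
#' @export
scaling_factors <- function(x_control, x_drug, g_ref = conductance_set()) {
  gc_ <- unclass(denormalize_conductances(as.numeric(x_control), g_ref))
  gd_ <- unclass(denormalize_conductances(as.numeric(x_drug), g_ref))
  zero <- gc_ == 0
  if (any(zero))
    stop("control conductance is zero for: ",
         paste(conductance_names()[zero], collapse = ", "),
         "; scaling factor undefined")
  structure(gd_ / gc_, class = "scaling_factors")
}
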