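#' Normalize conductance scale factors
#'
#' Maps conductance scale factors affinely onto the emulator's normalized
#' input space: `x_i = g_i / (2 * g_ref_i) - 0.5`, so that `x = 0`
#' corresponds to the reference (baseline) values and the physical range
#' `[0, 2] * g_ref` maps onto `[-0.5, 0.5]`.
#'
#' @param g a [conductance_set()] (or coercible vector).
#' @param g_ref the reference conductance set (strictly positive).
#' @return Numeric vector of 9 normalized coordinates in `[-0.5, 0.5]`.
#' @export
normalize_conductances <- function(g, g_ref = conductance_set()) {
  g <- as_conductance_set(g); g_ref <- as_conductance_set(g_ref)
  if (any(g_ref <= 0)) stop("g_ref must be strictly positive")
  x <- unclass(g) / (2 * unclass(g_ref)) - 0.5
  if (any(x < -0.5 - 1e-12) || any(x > 0.5 + 1e-12))
    stop("normalized conductances fall outside [-0.5, 0.5]")
  x
}

#' @rdname normalize_conductances
#' @param x normalized coordinates in `[-0.5, 0.5]`.
#' @export
denormalize_conductances <- function(x, g_ref = conductance_set()) {
  g_ref <- as_conductance_set(g_ref)
  if (any(g_ref <= 0)) stop("g_ref must be strictly positive")
  as_conductance_set(2 * unclass(g_ref) * (x + 0.5))
}

#' Initialize emulator weights
#'
#' Creates the two-stage network: an encoder of four fully connected layers
#' of width 256 mapping the nine normalized conductances to a 256-
#' dimensional latent code plus three depolarization parameters, and a
#' time-conditioned decoder of four fully connected layers of width 64
#' (ELU activations, tanh on the last hidden layer) followed by a linear
#' map to the membrane potential.  Weights use fan-in uniform
#' initialization.
#'
#' @param seed RNG seed for the initialization.
#' @param g_ref reference conductances stored with the weights.
#' @param latent_dim latent code dimension.
#' @return An object of class `emulator_weights`.
#' @export
init_emulator_weights <- function(seed = 1L, g_ref = conductance_set(),
                                  latent_dim = 256L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  theta1 <- mlp_init(c(9, 256, 256, 256, latent_dim + 3),
                     c("elu", "elu", "elu", "linear"))
  theta2 <- mlp_init(c(latent_dim + 8, 64, 64, 64, 64, 1),
                     c("elu", "elu", "elu", "tanh", "linear"))
  structure(list(theta1 = theta1, theta2 = theta2,
                 g_ref = as_conductance_set(g_ref),
                 latent_dim = as.integer(latent_dim),
                 t_center = 495, t_scale = 505, vm_scale = 100,
                 t_domain = c(-10, 1000),
                 provenance = list(init_seed = seed)),
            class = "emulator_weights")
}

#' @export
print.emulator_weights <- function(x, ...) {
  np <- sum(vapply(c(x$theta1, x$theta2),
                   function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("<emulator_weights> latent dim %d, %d parameters\n",
              x$latent_dim, np))
  invisible(x)
}

# polynomial time encoding: powers 1..8 of the normalized time
time_features <- function(t, w) {
  tt <- (t - w$t_center) / w$t_scale
  outer(tt, seq_len(8), "^")
}

#' Encode normalized conductances into a latent code
#'
#' Runs the encoder network, returning the latent code and the
#' depolarization parameters: slope `d1` (1/ms) and amplitude `d3` (mV)
#' are made positive through a softplus; offset `d2` (ms) is unconstrained.
#'
#' @param x normalized conductances (length-9 vector or n x 9 matrix).
#' @param w an `emulator_weights` object.
#' @return A list of class `latent_code` with `theta` (n x latent_dim
#'   matrix), `d1`, `d2`, `d3` (vectors), and the raw encoder outputs.
#' @export
encode <- function(x, w) {
  stopifnot(inherits(w, "emulator_weights"))
  X <- if (is.matrix(x)) x else matrix(x, 1)
  if (ncol(X) != 9) stop("x must have nine coordinates")
  if (any(!vapply(w$theta1, function(l) all(is.finite(l$W)) && all(is.finite(l$b)),
                  logical(1))))
    stop("encoder weights contain non-finite values")
  enc <- mlp_forward(w$theta1, X, keep_cache = FALSE)
  ld <- w$latent_dim
  structure(list(theta = enc$out[, seq_len(ld), drop = FALSE],
                 d1 = softplus(enc$out[, ld + 1]),
                 d2 = enc$out[, ld + 2],
                 d3 = w$vm_scale * softplus(enc$out[, ld + 3])),
            class = "latent_code")
}

# production evaluation path: fused C++ forward/backward.  `times` may be a
# shared vector or a (B x T) matrix of per-sample evaluation times.
emu_eval <- function(w, X, times, target = NULL, want_grads = FALSE,
                     want_x_grad = FALSE, want_t_grad = FALSE,
                     precision = c("double", "single")) {
  precision <- match.arg(precision)
  if (!is.matrix(times))
    times <- matrix(times, nrow(X), length(times), byrow = TRUE)
  .cpp_emu_eval(w$theta1, w$theta2, X, times, target,
                w$vm_scale, w$t_center, w$t_scale,
                want_grads, want_x_grad, want_t_grad,
                precision == "single")
}

# reference R implementation of the forward pass for a batch: B conductance
# points evaluated at a shared time vector.  Returns predictions (B x T)
# and the caches required by emu_backward().  Used for small problems and
# as the independent cross-check of the C++ path in the tests.
emu_forward <- function(w, X, times, keep_cache = TRUE) {
  B <- nrow(X); Tn <- length(times)
  enc <- mlp_forward(w$theta1, X, keep_cache = keep_cache)
  ld <- w$latent_dim
  raw1 <- enc$out[, ld + 1]; raw2 <- enc$out[, ld + 2]; raw3 <- enc$out[, ld + 3]
  d1 <- softplus(raw1); d2 <- raw2; d3 <- w$vm_scale * softplus(raw3)
  feats <- time_features(times, w)
  idx_s <- rep(seq_len(B), each = Tn)
  idx_t <- rep(seq_len(Tn), times = B)
  Z <- cbind(enc$out[idx_s, seq_len(ld), drop = FALSE],
             feats[idx_t, , drop = FALSE])
  dec <- mlp_forward(w$theta2, Z, keep_cache = keep_cache)
  f <- matrix(dec$out * w$vm_scale, B, Tn, byrow = TRUE)
  u <- outer(d1 / 2, times) - (d1 * d2 / 2)       # (d1/2) * (t - d2), B x T
  th <- tanh(u)
  pred <- f + (d3 / 2) * th
  list(pred = pred, enc = enc, dec = dec, times = times, feats = feats,
       d1 = d1, d2 = d2, d3 = d3, raw1 = raw1, raw3 = raw3, th = th,
       B = B, Tn = Tn, idx_s = idx_s)
}

# reverse pass: dPred is dL/dVm (B x T).  Returns parameter gradients for
# both networks, the gradient with respect to the normalized conductances
# (B x 9), and optionally the per-sample gradient with respect to a shared
# time shift (dL/dt accumulated over the grid).
emu_backward <- function(w, fwd, dPred, want_t_grad = FALSE) {
  B <- fwd$B; Tn <- fwd$Tn; ld <- w$latent_dim
  dOut <- matrix(as.vector(t(dPred)) * w$vm_scale, ncol = 1)
  bwd2 <- mlp_backward(w$theta2, fwd$dec$cache, dOut)
  dLatent <- rowsum(bwd2$dX[, seq_len(ld), drop = FALSE], fwd$idx_s,
                    reorder = TRUE)
  sech2 <- 1 - fwd$th^2
  tmd2 <- outer(rep(1, B), fwd$times) - fwd$d2    # t - d2, B x T
  dd3 <- rowSums(dPred * fwd$th) / 2
  dd1 <- rowSums(dPred * (fwd$d3 / 2) * sech2 * tmd2 / 2)
  dd2 <- rowSums(dPred * (fwd$d3 / 2) * sech2) * (-fwd$d1 / 2)
  dEnc <- cbind(dLatent,
                dd1 * sigmoid(fwd$raw1),
                dd2,
                dd3 * w$vm_scale * sigmoid(fwd$raw3))
  bwd1 <- mlp_backward(w$theta1, fwd$enc$cache, dEnc)
  out <- list(grads1 = bwd1$grads, grads2 = bwd2$grads, dX = bwd1$dX)
  if (want_t_grad) {
    # dVm/dt through the polynomial time features and the tanh helper
    tt <- (fwd$times - w$t_center) / w$t_scale
    dfeat_dt <- outer(tt, seq_len(8), function(x, p) p * x^(p - 1)) / w$t_scale
    dZt <- bwd2$dX[, ld + seq_len(8), drop = FALSE]
    # row-wise dot with the feature derivative of the matching time
    contrib <- rowSums(dZt * dfeat_dt[rep(seq_len(Tn), times = B), ,
                                      drop = FALSE])
    poly_part <- rowsum(contrib, fwd$idx_s, reorder = TRUE)[, 1]
    depol_part <- rowSums(dPred * (fwd$d3 / 2) * sech2 * (fwd$d1 / 2))
    out$dt <- poly_part + depol_part
  }
  out
}

#' Emulate the membrane potential at arbitrary times
#'
#' Evaluates the emulator `Vm(t) = f_theta(t) + (d3/2) tanh((d1/2)(t - d2))`
#' for one normalized conductance point at the requested times.  Times
#' outside the trained domain `[-10, 1000]` ms trigger a warning but are
#' still evaluated.
#'
#' @param x normalized conductances (length 9).
#' @param t times in ms (vector).
#' @param w an `emulator_weights` object.
#' @return Numeric vector of emulated potentials in mV.
#' @export
emulate_vm <- function(x, t, w) {
  stopifnot(inherits(w, "emulator_weights"))
  if (any(t < w$t_domain[1] - 1e-9 | t > w$t_domain[2] + 1e-9))
    warning("times outside the trained domain [",
            w$t_domain[1], ", ", w$t_domain[2], "] ms")
  res <- emu_eval(w, matrix(x, 1), t)
  as.numeric(res$pred)
}

#' Emulate a full action potential on a time grid
#'
#' @param x normalized conductances (length 9).
#' @param time_grid times in ms (default the canonical training grid).
#' @param w an `emulator_weights` object.
#' @return An [ap_trace()].
#' @export
emulate_ap <- function(x, time_grid = canonical_grid(), w) {
  ap_trace(time_grid, emulate_vm(x, time_grid, w))
}

#' Save and load emulator weights
#'
#' Weights are stored as a single JSON file holding a metadata header
#' (layer shapes, normalization constants, reference conductances,
#' provenance) and the flattened layer parameters; loading verifies the
#' shape invariants.
#'
#' @param w an `emulator_weights` object.
#' @param path file path (conventionally `.apw.json`).
#' @return `load_weights` returns the restored `emulator_weights`.
#' @export
save_weights <- function(w, path) {
  stopifnot(inherits(w, "emulator_weights"))
  ser_net <- function(net) lapply(net, function(l)
    list(dim = dim(l$W), act = l$act, W = as.numeric(l$W), b = as.numeric(l$b)))
  obj <- list(meta = list(latent_dim = w$latent_dim, t_center = w$t_center,
                          t_scale = w$t_scale, vm_scale = w$vm_scale,
                          t_domain = w$t_domain,
                          g_ref = as.list(unclass(w$g_ref)),
                          provenance = w$provenance),
              theta1 = ser_net(w$theta1), theta2 = ser_net(w$theta2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_net <- function(net) lapply(net, function(ly) {
    d <- unlist(ly$dim)
    list(W = matrix(unlist(ly$W), d[1], d[2]), b = unlist(ly$b),
         act = as.character(ly$act))
  })
  m <- obj$meta
  w <- structure(list(theta1 = de_net(obj$theta1), theta2 = de_net(obj$theta2),
                      g_ref = as_conductance_set(unlist(m$g_ref)),
                      latent_dim = as.integer(m$latent_dim),
                      t_center = as.numeric(m$t_center),
                      t_scale = as.numeric(m$t_scale),
                      vm_scale = as.numeric(m$vm_scale),
                      t_domain = unlist(m$t_domain),
                      provenance = m$provenance),
                 class = "emulator_weights")
  check_weight_shapes(w)
  w
}

check_weight_shapes <- function(w) {
  ld <- w$latent_dim
  s1 <- c(9, 256, 256, 256, ld + 3)
  s2 <- c(ld + 8, 64, 64, 64, 64, 1)
  chk <- function(net, sizes, nm) {
    for (l in seq_along(net)) {
      if (!all(dim(net[[l]]$W) == c(sizes[l], sizes[l + 1])))
        stop(nm, " layer ", l, " has shape ",
             paste(dim(net[[l]]$W), collapse = "x"), ", expected ",
             sizes[l], "x", sizes[l + 1])
      if (length(net[[l]]$b) != sizes[l + 1]) stop(nm, " bias shape mismatch")
      if (!all(is.finite(net[[l]]$W)) || !all(is.finite(net[[l]]$b)))
        stop(nm, " layer ", l, " contains non-finite parameters")
    }
  }
  chk(w$theta1, s1, "encoder")
  chk(w$theta2, s2, "decoder")
  invisible(w)
}
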