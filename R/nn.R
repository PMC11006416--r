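# Minimal dense-network machinery used by the emulator: fully connected
# layers with ELU / tanh / identity activations, reverse-mode gradients for
# both parameters and inputs, and an Adam optimizer.  Everything operates on
# plain double matrices (rows = samples).

elu <- function(z) {
  pos <- z > 0
  out <- expm1(pmin(z, 0))
  out[pos] <- z[pos]
  out
}

# derivative of ELU expressed through its output a = elu(z)
elu_deriv_from_out <- function(a) {
  d <- a + 1
  d[a > 0] <- 1
  d
}

softplus <- function(x) {
  out <- log1p(exp(-abs(x)))
  pos <- x > 0
  out[pos] <- out[pos] + x[pos]
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# layer sizes: numeric vector c(n_in, h1, ..., n_out); acts: one per weight
# layer ("elu", "tanh", "linear").  Fan-in uniform initialization, driven by
# the current RNG state.
mlp_init <- function(sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1)
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1]
    lim <- 1 / sqrt(n_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
      b = stats::runif(n_out, -lim, lim),
      act = acts[l])
  }
  layers
}

# forward pass; returns network output and the per-layer caches needed for
# the backward pass (input and activation output of every layer)
mlp_forward <- function(layers, X, keep_cache = TRUE) {
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  A <- X
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    Z <- A %*% ly$W
    Z <- Z + rep(ly$b, each = nrow(Z))
    Anew <- switch(ly$act,
                   elu = elu(Z),
                   tanh = tanh(Z),
                   linear = Z,
                   stop("unknown activation ", ly$act))
    if (keep_cache) cache[[l]] <- list(X = A, A = Anew)
    A <- Anew
  }
  list(out = A, cache = cache)
}

# reverse-mode pass: dOut is dL/d(output); returns parameter gradients and
# the gradient with respect to the network input
mlp_backward <- function(layers, cache, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]; cc <- cache[[l]]
    dZ <- switch(ly$act,
                 elu = dA * elu_deriv_from_out(cc$A),
                 tanh = dA * (1 - cc$A^2),
                 linear = dA)
    grads[[l]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, ly$W)
  }
  list(grads = grads, dX = dA)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(layers) {
  list(t = 0L,
       m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)))
}

adam_step <- function(layers, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      layers[[l]][[p]] <- layers[[l]][[p]] -
        lr * (state$m[[l]][[p]] / c1) / (sqrt(state$v[[l]][[p]] / c2) + eps)
    }
  }
  list(layers = layers, state = state)
}
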