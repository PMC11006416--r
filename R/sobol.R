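# Unscrambled Sobol' low-discrepancy sequences (Gray-code construction with
# the Joe-Kuo direction numbers), 30-bit precision.  Only the first 10
# dimensions are tabulated, which covers the nine-dimensional conductance
# space used throughout the package.

# primitive polynomial degree s, coefficient code a, and initial direction
# integers m for dimensions 2..10 (dimension 1 is the van der Corput base-2
# sequence)
.sobol_dirs <- list(
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19))
)

.SOBOL_BITS <- 30L

# direction-number matrix V[k, j] = v_k for dimension j, as integers scaled
# by 2^(30 - k)
.sobol_vmat <- function(d, nbits = .SOBOL_BITS) {
  V <- matrix(0L, nbits, d)
  V[, 1] <- bitwShiftL(1L, nbits - seq_len(nbits))
  for (j in seq_len(d - 1)) {
    dir <- .sobol_dirs[[j]]
    s <- dir$s; a <- dir$a
    m <- integer(nbits)
    m[seq_len(min(s, nbits))] <- dir$m[seq_len(min(s, nbits))]
    if (nbits > s) {
      for (k in (s + 1):nbits) {
        mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s > 1) for (q in seq_len(s - 1)) {
          # a encodes the polynomial coefficients a_1..a_{s-1}, MSB first
          if (bitwAnd(bitwShiftR(a, s - 1L - q), 1L) == 1L)
            mk <- bitwXor(mk, bitwShiftL(m[k - q], q))
        }
        m[k] <- mk
      }
    }
    V[, j + 1] <- bitwShiftL(m, nbits - seq_len(nbits))
  }
  V
}

#' Sobol' sequence points
#'
#' Generates the first `n` points of the unscrambled d-dimensional Sobol'
#' sequence (including the initial all-zero point), optionally applying a
#' random digital shift for scrambling.
#'
#' @param n number of points.
#' @param d dimension (1..10).
#' @param scramble apply a seeded random digital-shift scrambling.
#' @param seed RNG seed used only when `scramble = TRUE`.
#' @return An `n x d` matrix with entries in `[0, 1)`.
#' @export
sobol_points <- function(n, d, scramble = FALSE, seed = NULL) {
  stopifnot(n >= 1, d >= 1, d <= 10)
  V <- .sobol_vmat(d)
  X <- matrix(0L, n, d)
  state <- integer(d)
  if (n > 1) {
    for (i in 2:n) {
      c <- 1L
      im1 <- i - 2L                      # ruler sequence: lowest zero bit of i-2
      while (bitwAnd(im1, 1L) == 1L) { im1 <- bitwShiftR(im1, 1L); c <- c + 1L }
      state <- bitwXor(state, V[c, ])
      X[i, ] <- state
    }
  }
  if (scramble) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    shift <- as.integer(floor(stats::runif(d) * 2^.SOBOL_BITS))
    for (j in seq_len(d)) X[, j] <- bitwXor(X[, j], shift[j])
  }
  X / 2^.SOBOL_BITS
}

#' Sobol' samples of conductance scale factors
#'
#' Draws `n` nine-dimensional Sobol' points and maps them affinely to
#' `[low, high]^9`, yielding a deterministic low-discrepancy design of
#' conductance sets.
#'
#' @param n number of samples.
#' @param low,high bounds of the sampling box, `0 <= low < high <= 2`.
#' @param scramble,seed see [sobol_points()]; the plain deterministic
#'   sequence is used by default.
#' @param skip number of initial points of the sequence to drop.
#' @return List of `n` [conductance_set()] objects.
#' @export
#' @examples
#' g <- sobol_conductance_samples(4, 0.5, 1.5)
sobol_conductance_samples <- function(n, low = 0, high = 2, scramble = FALSE,
                                      seed = NULL, skip = 0) {
  if (!(low >= 0 && low < high && high <= 2))
    stop("bounds must satisfy 0 <= low < high <= 2")
  stopifnot(n >= 1, skip >= 0)
  P <- sobol_points(n + skip, 9, scramble = scramble, seed = seed)
  if (skip > 0) P <- P[-seq_len(skip), , drop = FALSE]
  lapply(seq_len(n), function(i) as_conductance_set(low + (high - low) * P[i, ]))
}
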