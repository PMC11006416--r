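#' Canonical non-uniform training time grid
#'
#' Training traces are extended to `t = -10` ms (holding the resting value)
#' and resampled non-uniformly to emphasize the depolarization phase:
#' 4 kHz on `[-10, -5)`, 10 kHz on `[-5, 20)` and 4 kHz on `[20, 1000]`,
#' giving 4191 points.
#'
#' @return Numeric vector of 4191 strictly increasing times in ms.
#' @export
canonical_grid <- function() {
  c(seq(-10, -5.25, by = 0.25),
    seq(-5, 19.9, by = 0.1),
    seq(20, 1000, by = 0.25))
}

#' Repolarization-failure criterion
#'
#' A trace is flagged as unrepolarized when the absolute transmembrane
#' potential difference between `t = 0` and `t = 1000` ms exceeds 10 % of
#' the trace amplitude (max minus min).  Such traces are far from full
#' repolarization and are excluded from the training corpus.  The
#' comparison is a strict inequality: a difference of exactly 10 % of the
#' amplitude is not flagged.
#'
#' @param trace an [ap_trace()] covering `[0, 1000]` ms.
#' @param threshold fraction of the amplitude (default 0.10).
#' @return logical flag.
#' @export
is_unrepolarized <- function(trace, threshold = 0.10) {
  if (min(trace$times) > 0 || max(trace$times) < 1000)
    stop("trace must cover [0, 1000] ms")
  v0 <- trace_at(trace, 0)
  v1 <- trace_at(trace, 1000)
  amp <- max(trace$vm) - min(trace$vm)
  abs(v1 - v0) > threshold * amp
}

#' Extend and resample a trace onto the canonical grid
#'
#' Holds the potential constant at `vm(0)` on `[-10, 0)` and linearly
#' interpolates the simulated samples onto the canonical non-uniform grid
#' of [canonical_grid()].  A trace already on the canonical grid is
#' reproduced exactly.
#'
#' @param trace an [ap_trace()] covering `[0, 1000]` ms.
#' @return An `ap_trace` on the canonical 4191-point grid.
#' @export
extend_and_resample <- function(trace) {
  grid <- canonical_grid()
  tmin <- min(trace$times)
  if (tmin > 0 || max(trace$times) < 1000)
    stop("trace must cover [0, 1000] ms")
  dt_in <- max(diff(trace$times))
  if (tmin >= -10 + 1e-9 && dt_in > 0.1 + 1e-9)
    stop("input sampling (", dt_in,
         " ms) is coarser than the 10 kHz depolarization window")
  v0 <- trace_at(trace, 0)
  vm <- numeric(length(grid))
  pre <- grid < tmin
  vm[pre] <- v0
  vm[!pre] <- stats::approx(trace$times, trace$vm, xout = grid[!pre])$y
  ap_trace(grid, vm, cycle_length = trace$cycle_length, beat = trace$beat)
}

#' Build the supervised training corpus
#'
#' Draws Sobol' conductance samples over one or more ranges, simulates each
#' to its (approximate) limit cycle, drops traces that fail the
#' repolarization criterion of [is_unrepolarized()] as well as simulator
#' failures, and resamples the survivors onto the canonical grid.
#'
#' @param n_total total number of conductance samples, divided equally
#'   among `ranges`.
#' @param ranges list of `c(low, high)` sampling boxes; the default mirrors
#'   the two-range design of half the samples in `[0, 2]` and half in
#'   `[0.5, 1.5]`.
#' @param protocol a [pacing_protocol()].
#' @param seed recorded in the provenance (the Sobol' design itself is
#'   deterministic and unscrambled).
#' @param progress print progress every `progress` samples (0 = quiet).
#' @return An `ap_dataset`: list with `grid` (canonical times), `vm`
#'   (n x 4191 matrix), `conductances` (n x 9 matrix), `split` (character
#'   vector, all `"train"` until [train_val_split()]), and `provenance`
#'   (ranges, seed, exclusion counts).
#' @export
build_training_set <- function(n_total = 4000,
                               ranges = list(c(0, 2), c(0.5, 1.5)),
                               protocol = pacing_protocol(),
                               seed = 1L, progress = 0) {
  stopifnot(n_total >= length(ranges))
  n_per <- rep(n_total %/% length(ranges), length(ranges))
  n_per[1] <- n_per[1] + n_total - sum(n_per)
  samples <- list()
  for (i in seq_along(ranges)) {
    r <- ranges[[i]]
    samples <- c(samples, sobol_conductance_samples(n_per[i], r[1], r[2]))
  }
  grid <- canonical_grid()
  vm <- matrix(NA_real_, length(samples), length(grid))
  keep <- logical(length(samples))
  n_unrep <- 0L; n_fail <- 0L
  for (i in seq_along(samples)) {
    tr <- tryCatch(simulate_ap(samples[[i]], protocol), error = function(e) NULL)
    if (is.null(tr)) { n_fail <- n_fail + 1L; next }
    if (is_unrepolarized(tr)) { n_unrep <- n_unrep + 1L; next }
    vm[i, ] <- extend_and_resample(tr)$vm
    keep[i] <- TRUE
    if (progress > 0 && i %% progress == 0)
      message("simulated ", i, "/", length(samples))
  }
  conductances <- do.call(rbind, lapply(samples, as.numeric))
  colnames(conductances) <- conductance_names()
  structure(list(
    grid = grid,
    vm = vm[keep, , drop = FALSE],
    conductances = conductances[keep, , drop = FALSE],
    split = rep("train", sum(keep)),
    provenance = list(ranges = ranges, seed = seed,
                      n_simulated = length(samples), n_kept = sum(keep),
                      n_excluded_unrepolarized = n_unrep,
                      n_excluded_failure = n_fail)),
    class = "ap_dataset")
}

#' @export
print.ap_dataset <- function(x, ...) {
  cat(sprintf("<ap_dataset> %d samples x %d grid points (%d train / %d validation)\n",
              nrow(x$vm), length(x$grid), sum(x$split == "train"),
              sum(x$split == "validation")))
  invisible(x)
}

#' Randomly label a validation split
#'
#' Randomly labels `floor(val_fraction * n)` samples as `"validation"`,
#' the rest as `"train"`.
#'
#' @param dataset an `ap_dataset`.
#' @param val_fraction fraction of samples held out, in (0, 1).
#' @param seed RNG seed; the split is reproducible given the seed.
#' @return The dataset with its `split` labels replaced.
#' @export
train_val_split <- function(dataset, val_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "ap_dataset"),
            val_fraction > 0, val_fraction < 1)
  n <- nrow(dataset$vm)
  n_val <- floor(val_fraction * n)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(n, n_val)
  dataset$split <- rep("train", n)
  dataset$split[idx] <- "validation"
  dataset$provenance$val_fraction <- val_fraction
  dataset$provenance$split_seed <- seed
  dataset
}

# subset view helpers
dataset_subset <- function(dataset, which = c("train", "validation")) {
  which <- match.arg(which)
  sel <- dataset$split == which
  list(vm = dataset$vm[sel, , drop = FALSE],
       conductances = dataset$conductances[sel, , drop = FALSE])
}

#' Per-biomarker ranges observed in a dataset
#'
#' Computes the seven biomarkers for every kept sample and returns the
#' min/max per biomarker, as used by the preprocessing quality filter on
#' control/drug pairs.
#'
#' @param dataset an `ap_dataset`.
#' @return A named list of `c(min, max)` per biomarker.
#' @export
dataset_biomarker_ranges <- function(dataset) {
  bms <- apply(dataset$vm, 1, function(v) {
    tryCatch(unclass(compute_biomarkers(ap_trace(dataset$grid, v))),
             error = function(e) rep(NA_real_, 7))
  })
  rownames(bms) <- c("RMP", "dVmMax", "Peak", "APD40", "APD50", "APD90",
                     "Tri90_40")
  out <- apply(bms, 1, function(x) range(x, na.rm = TRUE), simplify = FALSE)
  lapply(out, as.numeric)
}

#' Read and write datasets in a plain-text directory layout
#'
#' The dataset directory contains `grid.csv`, `vm.csv`, `conductances.csv`,
#' `split.csv` and `meta.json` (provenance).
#'
#' @param dataset an `ap_dataset`.
#' @param dir directory path (created if needed).
#' @return `read_dataset` returns an `ap_dataset`; `write_dataset` returns
#'   `dir` invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(list(t = dataset$grid)),
                     file.path(dir, "grid.csv"))
  data.table::fwrite(data.table::as.data.table(dataset$vm),
                     file.path(dir, "vm.csv"))
  data.table::fwrite(data.table::as.data.table(dataset$conductances),
                     file.path(dir, "conductances.csv"))
  data.table::fwrite(data.table::as.data.table(list(split = dataset$split)),
                     file.path(dir, "split.csv"))
  jsonlite::write_json(dataset$provenance, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  grid <- data.table::fread(file.path(dir, "grid.csv"))[[1]]
  vm <- as.matrix(data.table::fread(file.path(dir, "vm.csv")))
  g <- as.matrix(data.table::fread(file.path(dir, "conductances.csv")))
  split <- data.table::fread(file.path(dir, "split.csv"))[[1]]
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dimnames(vm) <- NULL
  structure(list(grid = grid, vm = vm, conductances = g, split = split,
                 provenance = meta),
            class = "ap_dataset")
}
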