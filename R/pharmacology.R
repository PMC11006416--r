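#' Synthetic drug definitions
#'
#' A synthetic drug is a set of per-target scaling factors over the nine
#' conductance targets; untouched targets have factor 1.  `random_drug`
#' draws a drug with `n_targets` distinct targets chosen uniformly without
#' replacement and factors uniform in `[low, high]`, emulating the
#' four-target random drug design.
#'
#' @param factors named numeric vector of scaling factors (subset of the
#'   nine target names); unnamed targets default to 1.
#' @return A named numeric vector of 9 factors, class `synthetic_drug`.
#' @export
#' @examples
#' synthetic_drug(c(gKr = 0.05, pCa = 1.2))
synthetic_drug <- function(factors = numeric(0)) {
  nm <- conductance_names()
  s <- stats::setNames(rep(1, 9), nm)
  if (length(factors)) {
    if (is.null(names(factors)) || !all(names(factors) %in% nm))
      stop("factors must be named by conductance targets")
    if (any(factors < 0)) stop("scaling factors must be >= 0")
    s[names(factors)] <- factors
  }
  structure(s, class = "synthetic_drug")
}

#' @rdname synthetic_drug
#' @param n_targets number of affected targets (1..9).
#' @param low,high factor bounds (`0.5` = 50 % block, `1.5` = 50 %
#'   enhancement).
#' @param seed optional RNG seed.
#' @export
random_drug <- function(n_targets = 4, low = 0.5, high = 1.5, seed = NULL) {
  stopifnot(n_targets >= 1, n_targets <= 9)
  if (!(low >= 0 && low < high)) stop("invalid factor bounds")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  targets <- sample(conductance_names(), n_targets)
  synthetic_drug(stats::setNames(stats::runif(n_targets, low, high), targets))
}

#' The ten-drug hERG/Cav1.2 block grid
#'
#' The fixed grid of ten synthetic drugs blocking the rapid delayed
#' rectifier (gKr scaled 0.05 to 0.14 in steps of 0.01) while enhancing the
#' L-type calcium current (pCa scaled 1.20 to 1.38 in steps of 0.02), used
#' to probe early-afterdepolarization behaviour.
#'
#' @return List of 10 `synthetic_drug`s.
#' @export
ead_drug_grid <- function() {
  lapply(1:10, function(i)
    synthetic_drug(c(gKr = 0.05 + 0.01 * (i - 1), pCa = 1.20 + 0.02 * (i - 1))))
}

#' Apply a drug to a conductance set
#'
#' Element-wise product of the control conductances with the drug's
#' scaling factors.  Results falling outside the simulator's `[0, 2]`
#' domain are clipped with a warning.
#'
#' @param g a [conductance_set()].
#' @param drug a [synthetic_drug()].
#' @return The drugged `conductance_set`.
#' @export
apply_drug <- function(g, drug) {
  g <- as_conductance_set(g)
  stopifnot(inherits(drug, "synthetic_drug"))
  out <- unclass(g) * unclass(drug)
  if (any(out > 2)) {
    warning("drugged conductances clipped to the [0, 2] domain")
    out <- pmin(out, 2)
  }
  as_conductance_set(out)
}

#' Build an experimentally calibrated synthetic cardiomyocyte population
#'
#' Walks the Sobol' sequence over the sampling box and accepts, in sequence
#' order, conductance sets whose paced APs show no repolarization
#' abnormality over the last two beats and whose biomarkers fall within
#' the experimental ranges, until `n` members are found.
#'
#' @param n population size.
#' @param ranges biomarker acceptance ranges, default [biomarker_ranges()].
#' @param low,high Sobol' sampling bounds (default `[0.5, 1.5]`).
#' @param protocol a [pacing_protocol()].
#' @param max_candidates abort with a calibration-failure error if fewer
#'   than 1 % of this many candidates are accepted.
#' @return A list of class `cell_population`: `members` (conductance
#'   sets), `biomarkers` (list of biomarker sets), `traces` (last-beat
#'   `ap_trace` per member) and `provenance` (candidate counts and
#'   acceptance rate).
#' @export
build_population <- function(n = 100, ranges = biomarker_ranges(),
                             low = 0.5, high = 1.5,
                             protocol = pacing_protocol(),
                             max_candidates = 10000) {
  members <- list(); bms <- list(); traces <- list()
  tried <- 0L
  batch <- 256L
  offset <- 0L
  while (length(members) < n) {
    cands <- sobol_conductance_samples(batch, low, high, skip = offset)
    offset <- offset + batch
    for (g in cands) {
      tried <- tried + 1L
      if (tried > max_candidates && length(members) / tried < 0.01)
        stop("population calibration failure: acceptance rate ",
             signif(length(members) / tried, 2), " after ", tried,
             " candidates")
      res <- tryCatch({
        ap1 <- simulate_ap(g, protocol)
        # penultimate beat for the two-beat abnormality check
        st <- attr(ap1, "state")
        ap2 <- integrate_beat(st, g, protocol)$trace
        list(ap1 = ap1, ap2 = ap2)
      }, error = function(e) NULL)
      if (is.null(res)) next
      if (detect_abnormality(list(res$ap1, res$ap2))) next
      b <- tryCatch(compute_biomarkers(res$ap2), error = function(e) NULL)
      if (is.null(b) || !within_ranges(b, ranges)) next
      members[[length(members) + 1L]] <- g
      bms[[length(bms) + 1L]] <- b
      traces[[length(traces) + 1L]] <- res$ap2
      if (length(members) >= n) break
    }
  }
  structure(list(members = members, biomarkers = bms, traces = traces,
                 provenance = list(n = n, bounds = c(low, high),
                                   candidates_tried = tried,
                                   acceptance_rate = n / tried)),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d members (acceptance rate %.2f)\n",
              length(x$members), x$provenance$acceptance_rate))
  invisible(x)
}

#' Pore-block scaling factor from concentration-response parameters
#'
#' Converts a drug concentration, half-maximal inhibitory concentration
#' and Hill coefficient into a conductance scaling factor via the
#' pore-block model `s = 1 / (1 + (C / IC50)^h)`.
#'
#' @param concentration drug concentration `C` (same unit as `ic50`).
#' @param ic50 half-maximal inhibitory concentration.
#' @param hill Hill coefficient (> 0).
#' @param unit,ic50_unit optional unit labels; a mismatch is an error.
#' @return Scaling factor in `(0, 1]`.
#' @export
#' @examples
#' pore_block(30, ic50 = 30, hill = 1)    # half-maximal block
pore_block <- function(concentration, ic50, hill, unit = "nM",
                       ic50_unit = unit) {
  if (!identical(unit, ic50_unit))
    stop("concentration unit (", unit, ") does not match IC50 unit (",
         ic50_unit, ")")
  stopifnot(ic50 > 0, hill > 0, all(concentration >= 0))
  1 / (1 + (concentration / ic50)^hill)
}

#' Reference distribution of a scaling factor
#'
#' Wraps samples of a drug-target scaling factor (for example obtained by
#' applying [pore_block()] to sampled IC50/Hill pairs); the summary mean
#' and standard deviation are always recomputed from the samples.
#'
#' @param samples numeric vector of scaling-factor samples.
#' @param drug,target optional labels.
#' @return A list of class `reference_distribution` with `samples`, `mu`,
#'   `sigma`, `drug`, `target`.
#' @export
reference_distribution <- function(samples, drug = NA_character_,
                                   target = NA_character_) {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("empty sample set")
  structure(list(samples = samples, mu = mean(samples),
                 sigma = stats::sd(samples), drug = drug, target = target),
            class = "reference_distribution")
}

#' Read reference distributions from CSV
#'
#' The CSV has columns `drug`, `target`, `sample_value`; one
#' `reference_distribution` is built per (drug, target) pair.
#'
#' @param path file path.
#' @return Named list of `reference_distribution`s (`drug.target`).
#' @export
read_reference_distributions <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("drug", "target", "sample_value") %in% names(df)))
  out <- list()
  for (key in unique(paste(df$drug, df$target, sep = "."))) {
    sel <- paste(df$drug, df$target, sep = ".") == key
    out[[key]] <- reference_distribution(df$sample_value[sel],
                                         drug = df$drug[sel][1],
                                         target = df$target[sel][1])
  }
  out
}

#' Classify an estimated scaling factor against a reference distribution
#'
#' An estimate is classified as successful when it falls into the closed
#' interval `mu +/- (margin + sigma)` spanned by the reference
#' distribution's mean and standard deviation plus a fixed margin.
#'
#' @param s_est estimated scaling factor.
#' @param dist a [reference_distribution()].
#' @param margin additive margin (default 0.15).
#' @return logical flag.
#' @export
success_classify <- function(s_est, dist, margin = 0.15) {
  stopifnot(inherits(dist, "reference_distribution"))
  half <- margin + dist$sigma
  s_est >= dist$mu - half & s_est <= dist$mu + half
}

#' Tabulate successful and unsuccessful estimates per target
#'
#' @param flags logical vector of [success_classify()] outcomes.
#' @param targets character vector (same length) naming the drug target of
#'   each estimate.
#' @return A data frame with one column per target plus `Total`, and rows
#'   `Successful`, `Unsuccessful`, `Ratio` (successful / classified,
#'   rounded to two decimals).
#' @export
tabulate_success <- function(flags, targets) {
  stopifnot(length(flags) == length(targets))
  tg <- unique(targets)
  succ <- vapply(tg, function(t) sum(flags[targets == t]), integer(1))
  tot <- vapply(tg, function(t) sum(targets == t), integer(1))
  succ <- c(succ, Total = sum(succ))
  tot <- c(tot, Total = length(flags))
  out <- rbind(Successful = succ, Unsuccessful = tot - succ,
               Ratio = round(succ / tot, 2))
  as.data.frame(out)
}
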