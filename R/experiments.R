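#' Forward-problem evaluation on a synthetic population
#'
#' Applies each drug to each population member, simulates the ground-truth
#' drugged AP and emulates it from the drugged conductances, then reports
#' the per-AP trace RMSE, biomarker mismatches, and the confusion
#' statistics of early-afterdepolarization classification (simulated truth
#' versus emulated prediction).  APs whose simulated trace fails the
#' repolarization criterion are excluded, mirroring the synthetic-data
#' design.
#'
#' @param population a `cell_population` from [build_population()].
#' @param drugs list of [synthetic_drug()]s.
#' @param w trained `emulator_weights`.
#' @param protocol a [pacing_protocol()].
#' @param grid evaluation grid (default the canonical training grid).
#' @return A list of class `forward_report`: `rmse` (vector, one entry per
#'   evaluated AP), `ead` (`confusion_stats`), `biomarker_rmse` (per
#'   biomarker, over APs where both biomarker sets exist), `n_excluded`,
#'   and bookkeeping in `provenance`.
#' @export
run_forward_experiment <- function(population, drugs, w,
                                   protocol = pacing_protocol(),
                                   grid = canonical_grid()) {
  stopifnot(inherits(population, "cell_population"))
  if (length(drugs) == 0)
    return(structure(list(rmse = numeric(0), ead = NULL,
                          biomarker_rmse = NULL, n_excluded = 0L,
                          provenance = list(n_pairs = 0L)),
                     class = "forward_report"))
  rmses <- numeric(0)
  truth_flags <- logical(0); pred_flags <- logical(0)
  bm_sim <- NULL; bm_emu <- NULL
  n_excluded <- 0L; n_failed <- 0L
  for (drug in drugs) {
    for (g in population$members) {
      gd <- suppressWarnings(apply_drug(g, drug))
      sim <- tryCatch(simulate_ap(gd, protocol), error = function(e) NULL)
      if (is.null(sim)) { n_failed <- n_failed + 1L; next }
      if (is_unrepolarized(sim)) { n_excluded <- n_excluded + 1L; next }
      simc <- extend_and_resample(sim)
      x <- normalize_conductances(gd, w$g_ref)
      emu <- suppressWarnings(emulate_ap(x, grid, w))
      rmses <- c(rmses, rmse_trace(simc, emu, interpolate = TRUE))
      truth_flags <- c(truth_flags, detect_ead(simc))
      pred_flags <- c(pred_flags, detect_ead(emu))
      bs <- tryCatch(unclass(compute_biomarkers(simc)), error = function(e) NULL)
      be <- tryCatch(unclass(compute_biomarkers(emu)), error = function(e) NULL)
      if (!is.null(bs) && !is.null(be)) {
        bm_sim <- rbind(bm_sim, bs); bm_emu <- rbind(bm_emu, be)
      }
    }
  }
  bmr <- if (!is.null(bm_sim))
    vapply(seq_len(ncol(bm_sim)), function(j) rmse_vector(bm_sim[, j],
                                                          bm_emu[, j]),
           numeric(1))
  if (!is.null(bmr)) names(bmr) <- colnames(bm_sim)
  structure(list(rmse = rmses,
                 ead = confusion_stats(truth_flags, pred_flags),
                 ead_truth = truth_flags, ead_pred = pred_flags,
                 biomarker_rmse = bmr,
                 n_excluded = n_excluded,
                 provenance = list(n_members = length(population$members),
                                   n_drugs = length(drugs),
                                   n_pairs = length(rmses),
                                   n_failed = n_failed)),
            class = "forward_report")
}

#' @export
print.forward_report <- function(x, ...) {
  cat(sprintf("<forward_report> %d APs, mean RMSE %.3f mV, %d excluded\n",
              length(x$rmse), mean(x$rmse), x$n_excluded))
  if (!is.null(x$ead)) print(x$ead)
  invisible(x)
}

#' Inverse-problem evaluation on emulated control/drug pairs
#'
#' For each control/drug pair the control AP is fitted with baseline
#' initial guess and prior, the drugged AP is fitted starting from the
#' control estimate, and pharmacological scaling factors are computed as
#' conductance ratios.  Reports the per-coordinate error distributions
#' between estimated and ground-truth normalized conductances (control and
#' drug) and scaling factors.
#'
#' @param controls `n x 9` matrix (or list of conductance sets) of control
#'   conductances.
#' @param drugs list of [synthetic_drug()]s, one per control (recycled if
#'   length 1).
#' @param w trained `emulator_weights`.
#' @param cfg a [fit_config()].
#' @param grid shared target time grid for the emulated targets; the
#'   default subsamples the canonical grid and stays inside `[-5, 995]` ms
#'   so that small fitted time offsets do not push evaluations outside the
#'   trained domain.
#' @return A list of class `inverse_report`: error matrices `e_control`,
#'   `e_drug` (normalized scale) and `e_s` (ratio scale), their
#'   per-coordinate RMSEs, and mean fit RMSEs.
#' @export
run_inverse_experiment <- function(controls, drugs, w,
                                   cfg = desk_fit_config(),
                                   grid = {
                                     g <- canonical_grid()[seq(1, 4191, by = 14)]
                                     g[g >= -5 & g <= 995]
                                   }) {
  if (is.list(controls) && !is.matrix(controls))
    controls <- do.call(rbind, lapply(controls, as.numeric))
  n <- nrow(controls)
  if (length(drugs) == 1L) drugs <- rep(drugs, n)
  stopifnot(length(drugs) == n)
  if (n == 0 || length(drugs) == 0)
    return(structure(list(e_control = NULL, e_drug = NULL, e_s = NULL),
                     class = "inverse_report"))
  x_true_c <- t(apply(controls, 1, normalize_conductances, g_ref = w$g_ref))
  gd <- do.call(rbind, lapply(seq_len(n), function(i)
    as.numeric(suppressWarnings(apply_drug(as_conductance_set(controls[i, ]),
                                           drugs[[i]])))))
  x_true_d <- t(apply(gd, 1, normalize_conductances, g_ref = w$g_ref))
  # emulated targets on the shared grid
  tc <- emu_eval(w, x_true_c, grid)$pred
  td <- emu_eval(w, x_true_d, grid)$pred
  ctrl_traces <- lapply(seq_len(n), function(i) ap_trace(grid, tc[i, ]))
  drug_traces <- lapply(seq_len(n), function(i) ap_trace(grid, td[i, ]))
  fit_c <- estimate_control(ctrl_traces, w, cfg)
  fit_d <- estimate_drug(drug_traces, fit_c$x_hat, w, cfg)
  s_true <- do.call(rbind, lapply(seq_len(n), function(i)
    as.numeric(scaling_factors(x_true_c[i, ], x_true_d[i, ], w$g_ref))))
  s_est <- do.call(rbind, lapply(seq_len(n), function(i)
    as.numeric(scaling_factors(fit_c$x_hat[i, ], fit_d$x_hat[i, ], w$g_ref))))
  e_control <- fit_c$x_hat - x_true_c
  e_drug <- fit_d$x_hat - x_true_d
  e_s <- s_est - s_true
  colnames(e_control) <- colnames(e_drug) <- colnames(e_s) <- conductance_names()
  per_rmse <- function(E) apply(E, 2, function(col) sqrt(mean(col^2)))
  structure(list(e_control = e_control, e_drug = e_drug, e_s = e_s,
                 rmse_control = per_rmse(e_control),
                 rmse_drug = per_rmse(e_drug),
                 rmse_s = per_rmse(e_s),
                 fit_rmse_control = mean(fit_c$rmse),
                 fit_rmse_drug = mean(fit_d$rmse)),
            class = "inverse_report")
}

#' @export
print.inverse_report <- function(x, ...) {
  if (is.null(x$e_control)) { cat("<inverse_report> empty\n"); return(invisible(x)) }
  cat(sprintf(paste0("<inverse_report> %d pairs | max RMSE: control %.3f, ",
                     "drug %.3f, s %.3f\n"),
              nrow(x$e_control), max(x$rmse_control), max(x$rmse_drug),
              max(x$rmse_s)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `forward_report` or `inverse_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
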