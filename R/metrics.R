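#' Root-mean-squared error between two traces
#'
#' @param a,b [ap_trace()]s.  If the grids differ and `interpolate = TRUE`,
#'   `b` is linearly interpolated onto `a`'s grid over the overlapping
#'   window; otherwise differing grids are an error.
#' @param interpolate allow grid interpolation.
#' @return RMSE in mV.
#' @export
rmse_trace <- function(a, b, interpolate = FALSE) {
  stopifnot(inherits(a, "ap_trace"), inherits(b, "ap_trace"))
  if (isTRUE(all.equal(a$times, b$times))) {
    va <- a$vm; vb <- b$vm
  } else if (interpolate) {
    sel <- a$times >= min(b$times) & a$times <= max(b$times)
    if (!any(sel)) stop("traces have no overlapping time window")
    va <- a$vm[sel]
    vb <- stats::approx(b$times, b$vm, xout = a$times[sel])$y
  } else {
    stop("traces are on different grids (set interpolate = TRUE)")
  }
  sqrt(mean((va - vb)^2))
}

#' Root-mean-squared error between two numeric vectors
#'
#' `sqrt(sum((u - v)^2) / N)`, used for biomarker vectors, normalized
#' conductances and scaling factors.
#'
#' @param u,v equal-length numeric vectors.
#' @return The scalar RMSE.
#' @export
rmse_vector <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  sqrt(mean((as.numeric(u) - as.numeric(v))^2))
}

#' Confusion statistics for a binary classification
#'
#' Counts true/false positives/negatives and derives sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy `(TP+TN)/total`,
#' reported as percentages rounded to one decimal.
#'
#' @param truth,predicted equal-length logical vectors.
#' @return A list of class `confusion_stats` with `TP`, `FN`, `FP`, `TN`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_stats <- function(truth, predicted) {
  if (!length(truth) || length(truth) != length(predicted))
    stop("truth and predicted must be non-empty and of equal length")
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  tp <- sum(truth & predicted); fn <- sum(truth & !predicted)
  fp <- sum(!truth & predicted); tn <- sum(!truth & !predicted)
  structure(list(TP = tp, FN = fn, FP = fp, TN = tn,
                 sensitivity = round(100 * tp / (tp + fn), 1),
                 specificity = round(100 * tn / (tn + fp), 1),
                 accuracy = round(100 * (tp + tn) / length(truth), 1)),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf(paste0("<confusion_stats> TP %d FN %d FP %d TN %d | ",
                     "sens %.1f%% spec %.1f%% acc %.1f%%\n"),
              x$TP, x$FN, x$FP, x$TN, x$sensitivity, x$specificity,
              x$accuracy))
  invisible(x)
}
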