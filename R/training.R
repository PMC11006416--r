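#' Training loss (mean-squared error over a time subset)
#'
#' The supervised loss is `L = 1/(2|T|) * sum_samples sum_t (pred - target)^2`
#' where `|T|` is the number of time points considered.  It is non-negative
#' and zero iff the prediction matches the target exactly.
#'
#' @param predicted,target numeric matrices (samples x times) or vectors of
#'   equal shape.
#' @return The scalar loss.
#' @export
mse_loss <- function(predicted, target) {
  if (length(predicted) != length(target))
    stop("predicted and target must have the same length")
  nt <- if (is.matrix(predicted)) ncol(predicted) else length(predicted)
  sum((predicted - target)^2) / (2 * nt)
}

#' Training configuration
#'
#' Schedules follow the reference recipe: the batch size grows linearly
#' from `batch_from` to `batch_to` over the epochs, and each gradient step
#' uses a random time subset whose fraction of the canonical grid grows
#' linearly from `tfrac_from` to `tfrac_to`.  Optimization uses Adam.
#'
#' @param epochs number of passes over the training split.
#' @param batch_from,batch_to batch-size schedule endpoints.
#' @param tfrac_from,tfrac_to time-subset fraction schedule endpoints.
#' @param lr Adam step size at the first epoch.
#' @param lr_final Adam step size at the last epoch; the step size decays
#'   geometrically between the two (constant when equal to `lr`).
#' @param beta1,beta2 Adam moment decay parameters.
#' @param seed RNG seed controlling initialization, shuffling and subset
#'   draws.
#' @param val_every validate (trace RMSE on the held-out split) every this
#'   many epochs; the best-validation checkpoint is returned.
#' @param init_seed seed for weight initialization (defaults to `seed`).
#' @param precision floating-point precision of the fused training step;
#'   `"single"` (the customary choice for network fitting, with the master
#'   weights and Adam state kept in double) or `"double"`.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 5000, batch_from = 1250, batch_to = 1800,
                            tfrac_from = 1 / 16, tfrac_to = 1,
                            lr = 1e-3, lr_final = lr, beta1 = 0.9,
                            beta2 = 0.999, seed = 1L, val_every = 50,
                            init_seed = seed,
                            precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(epochs >= 0, batch_from >= 1, batch_to >= batch_from,
            tfrac_from > 0, tfrac_to >= tfrac_from, tfrac_to <= 1, lr > 0,
            lr_final > 0)
  structure(as.list(environment()), class = "training_config")
}

#' Desk-scale training configuration
#'
#' A reduced schedule sized for a single CPU: small batches (64), a
#' constant 1/32 time subset, a geometrically decaying step size and
#' single-precision steps.  Many cheap gradient steps converge markedly
#' faster per unit time than fewer expensive ones; on the default
#' 4,000-sample corpus this configuration reaches a held-out mean trace
#' RMSE around 1 mV in 12-13 minutes on one CPU.
#'
#' @param epochs,seed,... overrides passed to [training_config()].
#' @return A `training_config`.
#' @export
desk_training_config <- function(epochs = 320, seed = 1L, ...) {
  training_config(epochs = epochs, batch_from = 64, batch_to = 64,
                  tfrac_from = 1 / 32, tfrac_to = 1 / 32,
                  lr = 3e-3, lr_final = 2e-4, seed = seed,
                  val_every = 32, ...)
}

#' Train the emulator on a dataset
#'
#' Minimizes the time-subset [mse_loss()] between emulated and simulated
#' action potentials over the training split with Adam, following the
#' batch-size and time-subset schedules of the configuration.  Validation
#' trace RMSE is computed every `val_every` epochs on the held-out split
#' and the best-validation checkpoint is returned.
#'
#' @param dataset an `ap_dataset` with a train/validation split (see
#'   [train_val_split()]).
#' @param config a [training_config()].
#' @param weights optionally, initialized or pre-trained
#'   `emulator_weights` to continue from.
#' @param verbose print progress.
#' @return An `emulator_weights` object with a `log` attribute: data frame
#'   of epoch, mean train loss, and validation RMSE (NA between
#'   validations).
#' @export
train_emulator <- function(dataset, config = desk_training_config(),
                           weights = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "ap_dataset"), inherits(config, "training_config"))
  tr <- dataset_subset(dataset, "train")
  va <- dataset_subset(dataset, "validation")
  if (nrow(tr$vm) == 0) stop("dataset has no training samples")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (is.null(weights))
    weights <- init_emulator_weights(seed = config$init_seed)
  set.seed(config$seed)
  w <- weights
  Xn <- t(apply(tr$conductances, 1, normalize_conductances, g_ref = w$g_ref))
  n <- nrow(Xn); Tn <- length(dataset$grid)
  st1 <- adam_init(w$theta1); st2 <- adam_init(w$theta2)
  log_epoch <- integer(0); log_loss <- numeric(0); log_val <- numeric(0)
  best_val <- Inf; best_w <- w
  frac_at <- function(e) if (config$epochs <= 1) config$tfrac_from else
    config$tfrac_from + (config$tfrac_to - config$tfrac_from) * (e - 1) / (config$epochs - 1)
  batch_at <- function(e) if (config$epochs <= 1) config$batch_from else
    round(config$batch_from + (config$batch_to - config$batch_from) * (e - 1) / (config$epochs - 1))
  lr_at <- function(e) if (config$epochs <= 1) config$lr else
    config$lr * (config$lr_final / config$lr)^((e - 1) / (config$epochs - 1))
  all_bs <- vapply(seq_len(config$epochs), function(e) min(batch_at(e), n),
                   numeric(1))
  all_nt <- vapply(seq_len(config$epochs), function(e)
    max(1, round(frac_at(e) * Tn)), numeric(1))
  all_lr <- vapply(seq_len(config$epochs), lr_at, numeric(1))
  if (config$precision == "single") {
    # fused compiled loop, run in blocks between validations
    m1 <- st1$m; v1 <- st1$v; m2 <- st2$m; v2 <- st2$v
    t_step <- 0L
    epoch <- 0L
    while (epoch < config$epochs) {
      eb <- seq(epoch + 1L, min(epoch + config$val_every, config$epochs))
      res <- .cpp_train_epochs(w$theta1, w$theta2, m1, v1, m2, v2, t_step,
                               Xn, tr$vm, dataset$grid,
                               as.integer(all_bs[eb]), as.integer(all_nt[eb]),
                               all_lr[eb], w$vm_scale, w$t_center, w$t_scale,
                               config$beta1, config$beta2)
      if (isTRUE(res$diverged))
        stop("training diverged (non-finite loss) near epoch ", max(eb))
      w$theta1 <- res$theta1; w$theta2 <- res$theta2
      m1 <- res$m1; v1 <- res$v1; m2 <- res$m2; v2 <- res$v2
      t_step <- res$t_step
      epoch <- max(eb)
      vrmse <- NA_real_
      if (nrow(va$vm) > 0) {
        vrmse <- validation_rmse(w, va, dataset$grid, chunk = 256L,
                                 precision = "single")
        if (vrmse < best_val) { best_val <- vrmse; best_w <- w }
      }
      log_epoch <- c(log_epoch, eb)
      log_loss <- c(log_loss, res$epoch_loss)
      log_val <- c(log_val, c(rep(NA_real_, length(eb) - 1), vrmse))
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.3f  val RMSE %s", epoch,
                        config$epochs, mean(res$epoch_loss),
                        ifelse(is.na(vrmse), "-", sprintf("%.3f mV", vrmse))))
    }
  } else {
    for (epoch in seq_len(config$epochs)) {
      bs <- all_bs[epoch]
      lr_e <- all_lr[epoch]
      nt_sub <- all_nt[epoch]
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1, n)]
        tsel <- sort(sample.int(Tn, nt_sub))
        res <- emu_eval(w, Xn[idx, , drop = FALSE], dataset$grid[tsel],
                        target = tr$vm[idx, tsel, drop = FALSE],
                        want_grads = TRUE, precision = config$precision)
        loss <- res$loss
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        losses <- c(losses, loss)
        bwd <- res
        up1 <- adam_step(w$theta1, bwd$grads1, st1, lr_e, config$beta1, config$beta2)
        w$theta1 <- up1$layers; st1 <- up1$state
        up2 <- adam_step(w$theta2, bwd$grads2, st2, lr_e, config$beta1, config$beta2)
        w$theta2 <- up2$layers; st2 <- up2$state
      }
      vrmse <- NA_real_
      if (nrow(va$vm) > 0 &&
          (epoch %% config$val_every == 0 || epoch == config$epochs)) {
        vrmse <- validation_rmse(w, va, dataset$grid)
        if (vrmse < best_val) { best_val <- vrmse; best_w <- w }
      }
      log_epoch <- c(log_epoch, epoch)
      log_loss <- c(log_loss, mean(losses))
      log_val <- c(log_val, vrmse)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.3f  val RMSE %s", epoch,
                        config$epochs, mean(losses),
                        ifelse(is.na(vrmse), "-", sprintf("%.3f mV", vrmse))))
    }
  }
  out <- if (is.finite(best_val)) best_w else w
  out$provenance$trained <- list(epochs = config$epochs, seed = config$seed,
                                 n_train = n, best_val_rmse = best_val)
  attr(out, "log") <- data.frame(epoch = log_epoch, train_loss = log_loss,
                                 val_rmse = log_val)
  out
}

#' Mean validation trace RMSE of an emulator on a sample set
#'
#' @param w trained `emulator_weights`.
#' @param subset list with `vm` and `conductances` matrices (see
#'   [train_val_split()] / `dataset_subset`).
#' @param grid the time grid of `vm`.
#' @param chunk samples per forward-pass chunk (memory control).
#' @param precision floating-point precision of the forward passes.
#' @return Mean over samples of the per-trace RMSE in mV.
#' @export
validation_rmse <- function(w, subset, grid, chunk = 128L,
                            precision = c("double", "single")) {
  precision <- match.arg(precision)
  n <- nrow(subset$vm)
  stopifnot(n > 0)
  Xn <- t(apply(subset$conductances, 1, normalize_conductances, g_ref = w$g_ref))
  rmses <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    res <- emu_eval(w, Xn[idx, , drop = FALSE], grid, precision = precision)
    err <- res$pred - subset$vm[idx, , drop = FALSE]
    rmses[idx] <- sqrt(rowMeans(err^2))
  }
  mean(rmses)
}
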