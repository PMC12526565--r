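## LSTM autoencoder for inertial abnormality detection.
##
## Encoder: two stacked LSTM layers; the latent code is the concatenation of
## both layers' final hidden states (2 x hidden units; 256-dimensional at the
## default 128 hidden units). Decoder: the latent code is repeated at every
## timestep and passed through a symmetric two-layer LSTM stack whose
## concatenated per-timestep hidden states feed a dense output layer
## (2 x hidden -> 6 channels).

#' Build an LSTM autoencoder for 6-channel inertial windows
#'
#' @param input_dim Number of channels; fixed at 6 for this sensor layout.
#' @param hidden Hidden units per LSTM layer (default 128, giving a
#'   256-dimensional latent representation).
#' @param latent Latent dimension; must equal `2 * hidden`.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `fd_autoencoder`.
#' @export
fd_autoencoder <- function(input_dim = 6, hidden = 128, latent = 2 * hidden,
                           seed = 1) {
  .fd_assert(input_dim == 6,
             "input_dim is fixed at 6 for the 6-axis IMU (got %d)", input_dim)
  .fd_assert(latent == 2 * hidden,
             "latent dim must equal 2 * hidden (%d != 2 * %d)", latent, hidden)
  set.seed(fd_subseed(seed, 31L))
  params <- list()
  for (nm in names(p1 <- lstm_init(input_dim, hidden))) {
    params[[paste0("enc1_", nm)]] <- p1[[nm]]
  }
  for (nm in names(p2 <- lstm_init(hidden, hidden))) {
    params[[paste0("enc2_", nm)]] <- p2[[nm]]
  }
  for (nm in names(p3 <- lstm_init(2 * hidden, hidden))) {
    params[[paste0("dec1_", nm)]] <- p3[[nm]]
  }
  for (nm in names(p4 <- lstm_init(hidden, hidden))) {
    params[[paste0("dec2_", nm)]] <- p4[[nm]]
  }
  params$W_out <- glorot(2 * hidden, input_dim)
  params$b_out <- rep(0, input_dim)
  structure(list(params = params, hidden = hidden, input_dim = input_dim,
                 latent = latent, trained = FALSE, seed = seed),
            class = "fd_autoencoder")
}

#' @export
print.fd_autoencoder <- function(x, ...) {
  np <- length(fd_flatten(x$params))
  cat("LSTM autoencoder: 6 ->", x$hidden, "x2 ->", x$latent,
      "latent ->", x$hidden, "x2 -> 6 |", np, "parameters |",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

.ae_layer <- function(params, prefix) {
  list(W = params[[paste0(prefix, "_W")]],
       U = params[[paste0(prefix, "_U")]],
       b = params[[paste0(prefix, "_b")]])
}

## Forward pass on a (B, T, 6) batch. Returns reconstructions and caches.
ae_forward <- function(params, X, hidden) {
  B <- dim(X)[1]; Tt <- dim(X)[2]
  f1 <- lstm_forward(.ae_layer(params, "enc1"), X)
  f2 <- lstm_forward(.ae_layer(params, "enc2"), f1$H_seq)
  latent <- cbind(matrix(f1$H_seq[, Tt, ], B), matrix(f2$H_seq[, Tt, ], B))
  Drep <- array(0, c(B, Tt, 2 * hidden))
  for (t in seq_len(Tt)) Drep[, t, ] <- latent
  f3 <- lstm_forward(.ae_layer(params, "dec1"), Drep)
  f4 <- lstm_forward(.ae_layer(params, "dec2"), f3$H_seq)
  Xhat <- array(0, dim(X))
  for (t in seq_len(Tt)) {
    cat_t <- cbind(matrix(f3$H_seq[, t, ], B), matrix(f4$H_seq[, t, ], B))
    Xhat[, t, ] <- cat_t %*% params$W_out +
      matrix(params$b_out, B, length(params$b_out), byrow = TRUE)
  }
  list(Xhat = Xhat, f1 = f1, f2 = f2, f3 = f3, f4 = f4, latent = latent)
}

## Mean (over batch) of the per-window MSE; per-window MSE is the mean over
## timesteps of the squared Euclidean norm of the 6-channel residual.
ae_loss <- function(X, Xhat) {
  Tt <- dim(X)[2]
  per_window <- apply((X - Xhat)^2, 1, sum) / Tt
  list(loss = mean(per_window), per_window = per_window)
}

## Exact gradients of ae_loss via backprop through decoder and encoder.
ae_backward <- function(params, X, fwd, hidden) {
  B <- dim(X)[1]; Tt <- dim(X)[2]
  H <- hidden
  dXhat <- 2 * (fwd$Xhat - X) / (Tt * B)
  dW_out <- params$W_out * 0; db_out <- params$b_out * 0
  dH3 <- array(0, c(B, Tt, H)); dH4 <- array(0, c(B, Tt, H))
  for (t in seq_len(Tt)) {
    dy <- matrix(dXhat[, t, ], B)
    cat_t <- cbind(matrix(fwd$f3$H_seq[, t, ], B),
                   matrix(fwd$f4$H_seq[, t, ], B))
    dW_out <- dW_out + crossprod(cat_t, dy)
    db_out <- db_out + colSums(dy)
    dcat <- dy %*% t(params$W_out)
    dH3[, t, ] <- dcat[, 1:H, drop = FALSE]
    dH4[, t, ] <- dcat[, (H + 1):(2 * H), drop = FALSE]
  }
  b4 <- lstm_backward(.ae_layer(params, "dec2"), fwd$f4, dH4)
  dH3 <- dH3 + b4$dX
  b3 <- lstm_backward(.ae_layer(params, "dec1"), fwd$f3, dH3)
  ## decoder input is the latent repeated at every step
  dlatent <- matrix(0, B, 2 * H)
  for (t in seq_len(Tt)) dlatent <- dlatent + matrix(b3$dX[, t, ], B)
  dH2 <- array(0, c(B, Tt, H))
  dH2[, Tt, ] <- dlatent[, (H + 1):(2 * H), drop = FALSE]
  b2 <- lstm_backward(.ae_layer(params, "enc2"), fwd$f2, dH2)
  dH1 <- b2$dX
  dH1[, Tt, ] <- matrix(dH1[, Tt, ], B) + dlatent[, 1:H, drop = FALSE]
  b1 <- lstm_backward(.ae_layer(params, "enc1"), fwd$f1, dH1)
  grads <- list()
  for (pr in c("enc1", "enc2", "dec1", "dec2")) {
    bb <- switch(pr, enc1 = b1, enc2 = b2, dec1 = b3, dec2 = b4)
    grads[[paste0(pr, "_W")]] <- bb$dW
    grads[[paste0(pr, "_U")]] <- bb$dU
    grads[[paste0(pr, "_b")]] <- bb$db
  }
  grads$W_out <- dW_out
  grads$b_out <- db_out
  grads[names(params)]
}

## Stack a list of ImuWindows (each with $samples T x 6) into a (B, T, 6)
## array.
fd_stack_windows <- function(windows) {
  .fd_assert(length(windows) > 0, "empty window list")
  Tt <- nrow(windows[[1]]$samples)
  D <- ncol(windows[[1]]$samples)
  X <- array(0, c(length(windows), Tt, D))
  for (i in seq_along(windows)) X[i, , ] <- windows[[i]]$samples
  X
}

#' Train the autoencoder on non-fall inertial windows
#'
#' Minimizes the mean reconstruction error with Adam (defaults: learning rate
#' 0.001, batch size 32, up to 50 epochs, early stopping after 10 epochs
#' without validation improvement). A validation split is held out for early
#' stopping; the best-validation parameters are returned together with the
#' per-window training reconstruction errors needed for threshold
#' calibration.
#'
#' @param model An [fd_autoencoder()].
#' @param windows List of preprocessed non-fall windows (from
#'   [fd_make_windows()]), or a `(B, T, 6)` array.
#' @param lr,batch_size,epochs,patience Training recipe.
#' @param val_frac Fraction of windows held out for early stopping.
#' @param seed Integer seed (shuffling and split).
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `train_errors` (per-window MSE on the
#'   training windows under the returned parameters) and `history`.
#' @export
fd_train_autoencoder <- function(model, windows, lr = 1e-3, batch_size = 32,
                                 epochs = 50, patience = 10, val_frac = 0.1,
                                 seed = 1, verbose = FALSE) {
  .fd_assert(inherits(model, "fd_autoencoder"), "model must be fd_autoencoder")
  X <- if (is.array(windows) && length(dim(windows)) == 3) windows
       else fd_stack_windows(windows)
  .fd_assert(dim(X)[1] >= 2, "need at least 2 training windows")
  B <- dim(X)[1]
  set.seed(fd_subseed(seed, 41L))
  idx <- sample(B)
  n_val <- max(1L, floor(val_frac * B))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  if (length(tr_idx) == 0) { tr_idx <- val_idx }
  Xtr <- X[tr_idx, , , drop = FALSE]
  Xval <- X[val_idx, , , drop = FALSE]
  params <- model$params
  st <- adam_init(params)
  best <- list(params = params, val = Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  stale <- 0L
  for (ep in seq_len(epochs)) {
    set.seed(fd_subseed(seed, 41L, ep))
    ord <- sample(dim(Xtr)[1])
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      Xb <- Xtr[bi, , , drop = FALSE]
      fwd <- ae_forward(params, Xb, model$hidden)
      l <- ae_loss(Xb, fwd$Xhat)
      grads <- ae_backward(params, Xb, fwd, model$hidden)
      upd <- adam_step(params, grads, st, lr = lr)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + l$loss; nb <- nb + 1L
    }
    vl <- ae_loss(Xval, ae_forward(params, Xval, model$hidden)$Xhat)$loss
    hist <- rbind(hist, data.frame(epoch = ep, train = ep_loss / nb, val = vl))
    if (verbose) message(sprintf("epoch %d: train %.5f val %.5f",
                                 ep, ep_loss / nb, vl))
    if (vl < best$val - 1e-9) {
      best <- list(params = params, val = vl, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$stopped_epoch <- best$epoch
  fullfwd <- ae_forward(model$params, X, model$hidden)
  model$train_errors <- ae_loss(X, fullfwd$Xhat)$per_window
  model
}

#' Reconstruct windows and score their reconstruction error
#'
#' @param model A trained [fd_autoencoder()].
#' @param windows Window list or `(B, T, 6)` array.
#' @return Numeric vector of per-window MSE values.
#' @export
fd_reconstruction_errors <- function(model, windows) {
  X <- if (is.array(windows) && length(dim(windows)) == 3) windows
       else fd_stack_windows(windows)
  fwd <- ae_forward(model$params, X, model$hidden)
  ae_loss(X, fwd$Xhat)$per_window
}

#' Reconstruction error of one window
#'
#' Mean over the window's timesteps of the squared Euclidean norm of the
#' per-timestep 6-channel residual.
#'
#' @param x,xhat T x 6 matrices (input window and its reconstruction).
#' @return Nonnegative scalar.
#' @export
fd_reconstruction_mse <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  .fd_assert(all(dim(x) == dim(xhat)),
             "shape mismatch: %dx%d vs %dx%d",
             nrow(x), ncol(x), nrow(xhat), ncol(xhat))
  sum((x - xhat)^2) / nrow(x)
}

#' Calibrate the anomaly threshold from training reconstruction errors
#'
#' The threshold is the stated percentile (default 95th) of the training
#' reconstruction errors, under the linear-interpolation percentile
#' convention (`stats::quantile` type 7).
#'
#' @param errors Numeric vector of training reconstruction errors.
#' @param percentile Percentile in (0, 100].
#' @return Object of class `fd_threshold` with elements `tau`, `percentile`,
#'   `calibration_errors` and a `degraded` flag (fewer than 20 calibration
#'   values).
#' @export
fd_calibrate_tau <- function(errors, percentile = 95) {
  .fd_assert(length(errors) > 0, "empty calibration sample")
  .fd_assert(percentile > 0 && percentile <= 100,
             "percentile must be in (0, 100]")
  degraded <- length(errors) < 20
  if (degraded) {
    warning(sprintf("only %d calibration errors (< 20); threshold is degraded",
                    length(errors)), call. = FALSE)
  }
  tau <- unname(stats::quantile(errors, percentile / 100, type = 7))
  .fd_assert(tau > 0, "calibrated threshold must be positive (got %g)", tau)
  structure(list(tau = tau, percentile = percentile,
                 calibration_errors = errors, degraded = degraded),
            class = "fd_threshold")
}

#' Normalized anomaly score
#'
#' `s = min(mse / tau, 1)`; the binary abnormality flag is `mse > tau`
#' (strict).
#'
#' @param mse Nonnegative reconstruction error(s).
#' @param tau An [fd_calibrate_tau()] object or a positive scalar.
#' @return Data frame with columns `mse`, `score` in `[0, 1]`, `abnormal`.
#' @export
fd_anomaly_score <- function(mse, tau) {
  tv <- if (inherits(tau, "fd_threshold")) tau$tau else tau
  .fd_assert(is.numeric(tv) && tv > 0, "tau must be positive")
  .fd_assert(all(mse >= 0), "negative reconstruction error")
  data.frame(mse = mse, score = pmin(mse / tv, 1), abnormal = mse > tv)
}
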