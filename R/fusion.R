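## Decision-level fusion: the conjunctive threshold rule, epoch alignment of
## the two score streams, and the small trainable fusion head used for
## few-shot personalization.

#' Fusion configuration
#'
#' @param alpha Common decision threshold in (0, 1) applied to both the
#'   vision fall probability and the IMU anomaly score (default 0.70).
#' @param p_thresh Vision threshold; defaults to `alpha`.
#' @param epoch Decision epoch in seconds.
#' @return List of class `fd_fusion_config`.
#' @export
fd_fusion_config <- function(alpha = 0.70, p_thresh = alpha, epoch = 1) {
  .fd_assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(alpha = alpha, p_thresh = p_thresh, epoch = epoch),
            class = "fd_fusion_config")
}

#' Fuse the two branch scores into a decision label
#'
#' FALL when both the vision probability and the anomaly score strictly
#' exceed their thresholds; LOW_CONFIDENCE when exactly one does; NORMAL
#' otherwise. A missing anomaly score (`NA`, e.g. an IMU stream gap) can
#' never produce FALL: the rule is conjunctive, so the epoch is at most
#' LOW_CONFIDENCE on the strength of the vision branch alone.
#'
#' @param p_fall Vision fall probability in `[0, 1]` (vectorized).
#' @param s_anomaly IMU anomaly score in `[0, 1]` or `NA` (vectorized).
#' @param config An [fd_fusion_config()].
#' @return Character vector of labels (`"FALL"`, `"LOW_CONFIDENCE"`,
#'   `"NORMAL"`).
#' @export
fd_fuse <- function(p_fall, s_anomaly, config = fd_fusion_config()) {
  .fd_assert(all(p_fall >= 0 & p_fall <= 1, na.rm = TRUE),
             "p_fall outside [0, 1]")
  .fd_assert(all(is.na(p_fall)) == FALSE || length(p_fall) == 0,
             "p_fall must be observed")
  .fd_assert(all(s_anomaly >= 0 & s_anomaly <= 1, na.rm = TRUE),
             "s_anomaly outside [0, 1]")
  v <- p_fall > config$p_thresh
  s <- !is.na(s_anomaly) & s_anomaly > config$alpha
  ifelse(v & s, "FALL", ifelse(xor(v, s), "LOW_CONFIDENCE", "NORMAL"))
}

#' Pair per-segment vision outputs with per-window IMU scores
#'
#' For each 1-s vision segment, the paired anomaly score is the maximum
#' score among IMU windows whose centres fall within `tol` seconds of the
#' segment centre (the 1.2-s windows start every 0.6 s, so `tol = 0.6`
#' guarantees coverage for aligned streams). Pairing is total: a segment
#' with no window within tolerance receives `NA`.
#'
#' @param vision_centers Segment centre times (s).
#' @param imu_centers IMU window centre times (s).
#' @param imu_scores Anomaly scores, parallel to `imu_centers`.
#' @param tol Pairing tolerance (s).
#' @return Numeric vector of paired scores (NA where no window qualifies).
#' @export
fd_align_epochs <- function(vision_centers, imu_centers, imu_scores,
                            tol = 0.6) {
  .fd_assert(length(imu_centers) == length(imu_scores),
             "imu_centers and imu_scores differ in length")
  vapply(vision_centers, function(tc) {
    ## small epsilon so exact-tolerance distances are not lost to rounding
    near <- abs(imu_centers - tc) <= tol + 1e-9
    if (!any(near)) NA_real_ else max(imu_scores[near])
  }, numeric(1))
}

#' Trainable fusion head
#'
#' A small two-input multilayer perceptron (2 -> `hidden` tanh units -> 1
#' sigmoid) mapping `(p_fall, s_anomaly)` to a fall probability. Two hidden
#' units are initialized as sharp threshold detectors at `alpha` so that the
#' fresh head reproduces the conjunctive threshold rule (decisions match
#' [fd_fuse()]'s FALL-vs-rest mapping for score pairs at least 0.05 away
#' from `alpha`); the remaining units start near zero and give fine-tuning
#' capacity.
#'
#' @param alpha Threshold the initialization mimics.
#' @param hidden Hidden units (parameter count stays in the dozens, far
#'   below the 5k budget for on-device adaptation).
#' @param sharpness Slope of the threshold-mimicking units.
#' @param seed Integer seed for the auxiliary units.
#' @return Object of class `fd_fusion_head`.
#' @export
fd_fusion_head <- function(alpha = 0.70, hidden = 8, sharpness = 20,
                           seed = 1) {
  .fd_assert(hidden >= 2, "need at least 2 hidden units")
  set.seed(fd_subseed(seed, 71L))
  W1 <- matrix(stats::rnorm(2 * hidden, 0, 0.05), 2, hidden)
  b1 <- stats::rnorm(hidden, 0, 0.05)
  ## units 1-2: tanh(sharpness * (score - alpha)) for each input
  W1[, 1] <- c(sharpness, 0); b1[1] <- -sharpness * alpha
  W1[, 2] <- c(0, sharpness); b1[2] <- -sharpness * alpha
  w2 <- stats::rnorm(hidden, 0, 0.05)
  w2[1:2] <- 10
  b2 <- -10
  params <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  structure(list(params = params, alpha = alpha, hidden = hidden,
                 n_params = length(fd_flatten(params))),
            class = "fd_fusion_head")
}

#' @export
print.fd_fusion_head <- function(x, ...) {
  cat("Fusion head: 2 ->", x$hidden, "-> 1 (", x$n_params,
      "parameters ), AND-rule init at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Fall probability from the fusion head
#'
#' @param head An [fd_fusion_head()].
#' @param p_fall,s_anomaly Scores in `[0, 1]` (vectorized).
#' @return Fall probabilities in `[0, 1]`.
#' @export
fd_fusion_head_predict <- function(head, p_fall, s_anomaly) {
  .fd_assert(all(p_fall >= 0 & p_fall <= 1), "p_fall outside [0, 1]")
  .fd_assert(all(s_anomaly >= 0 & s_anomaly <= 1), "s_anomaly outside [0, 1]")
  X <- cbind(p_fall, s_anomaly)
  p <- head$params
  Hh <- tanh(X %*% p$W1 + matrix(p$b1, nrow(X), head$hidden, byrow = TRUE))
  as.numeric(sigmoid(Hh %*% p$w2 + p$b2))
}

#' Fine-tune the fusion head on labeled calibration score pairs
#'
#' Binary cross-entropy on the calibration pairs, full-batch Adam, exactly
#' `iterations` gradient steps (early exit only on numerically zero loss).
#' The default learning rate (0.05) is scaled to this head's small
#' parameterization; the encoders are untouched by construction — the head
#' only ever sees the two branch scores.
#'
#' @param head An [fd_fusion_head()].
#' @param p_fall,s_anomaly Calibration scores.
#' @param labels Binary labels (1 = fall epoch).
#' @param lr Learning rate.
#' @param iterations Gradient iterations.
#' @return The adapted head (`$loss_trace` records the loss per iteration).
#' @export
fd_fine_tune_head <- function(head, p_fall, s_anomaly, labels, lr = 0.05,
                              iterations = 50) {
  .fd_assert(length(p_fall) >= 1, "empty calibration set")
  .fd_assert(length(p_fall) == length(s_anomaly) &&
               length(p_fall) == length(labels),
             "calibration vectors differ in length")
  X <- cbind(p_fall, s_anomaly)
  y <- as.numeric(labels)
  params <- head$params
  st <- adam_init(params)
  n <- nrow(X)
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    Z1 <- X %*% params$W1 + matrix(params$b1, n, head$hidden, byrow = TRUE)
    Hh <- tanh(Z1)
    z2 <- as.numeric(Hh %*% params$w2 + params$b2)
    phat <- sigmoid(z2)
    eps <- 1e-12
    loss <- -mean(y * log(phat + eps) + (1 - y) * log(1 - phat + eps))
    trace[it] <- loss
    if (loss < 1e-10) { trace <- trace[seq_len(it)]; break }
    dz2 <- (phat - y) / n
    gw2 <- as.numeric(crossprod(Hh, dz2))
    gb2 <- sum(dz2)
    dH <- outer(dz2, params$w2)
    dZ1 <- dH * (1 - Hh * Hh)
    gW1 <- crossprod(X, dZ1)
    gb1 <- colSums(dZ1)
    upd <- adam_step(params, list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2),
                     st, lr = lr)
    params <- upd$params; st <- upd$state
  }
  head$params <- params
  head$loss_trace <- trace
  head
}
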