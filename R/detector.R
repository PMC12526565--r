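## The fitted bimodal detector: trains both branches on a cohort, calibrates
## the anomaly threshold, and scores new trials epoch by epoch.

#' Detector configuration
#'
#' All defaults equal the reference operating point: 60-sample IMU windows
#' (1.2 s at 50 Hz) with 50% overlap, 0.2-20 Hz 4th-order zero-phase
#' band-pass, 30-frame pose segments, visibility threshold 0.5, 95th-
#' percentile anomaly threshold, fusion threshold alpha = 0.70, 30-frame
#' prone vote. Network sizes and training recipes are configurable so that
#' scaled-down studies can run on modest hardware.
#'
#' @param window,overlap IMU windowing.
#' @param band,filter_order Band-pass design (Hz).
#' @param fs,fps Sampling rates (IMU Hz, video fps).
#' @param frames_per_segment Pose frames per 1-s segment.
#' @param visibility_threshold Landmark usability bound.
#' @param tau_percentile Calibration percentile for the anomaly threshold.
#' @param alpha Fusion threshold.
#' @param prone_required,occlusion_gap Temporal vote parameters.
#' @param vision_mode,attenuation Gating of the transformer probability by
#'   the posture vote.
#' @param ae_hidden,ae_lr,ae_batch,ae_epochs,ae_patience Autoencoder size
#'   and recipe.
#' @param tf_d_model,tf_layers,tf_heads,tf_lr,tf_batch,tf_epochs,tf_patience,tf_schedule
#'   Transformer size and recipe.
#' @param max_ae_windows,max_tf_segments Optional training-set subsampling
#'   caps (seeded) for scaled-down runs.
#' @param event_pad Seconds of post-event padding treated as fall when
#'   labeling windows/segments from a trial script.
#' @return List of class `fd_config`.
#' @export
fd_config <- function(window = 60, overlap = 0.5, band = c(0.2, 20),
                      filter_order = 4, fs = 50, fps = 30,
                      frames_per_segment = 30, visibility_threshold = 0.5,
                      tau_percentile = 95, alpha = 0.70,
                      prone_required = 30, occlusion_gap = 0,
                      vision_mode = "gated", attenuation = 0.5,
                      ae_hidden = 128, ae_lr = 1e-3, ae_batch = 32,
                      ae_epochs = 50, ae_patience = 10,
                      tf_d_model = 256, tf_layers = 4, tf_heads = 8,
                      tf_lr = 1e-4, tf_batch = 64, tf_epochs = 40,
                      tf_patience = 5, tf_schedule = "cosine",
                      max_ae_windows = Inf, max_tf_segments = Inf,
                      event_pad = 0) {
  cfg <- as.list(environment())
  class(cfg) <- "fd_config"
  cfg
}

#' Scaled-down study configuration
#'
#' The reference operating point with reduced network sizes and training
#' recipes sized for desk-scale studies on one CPU: an 8-unit-per-layer
#' autoencoder (16-dim latent), a single 2-head transformer layer at model
#' dimension 32 with a faster constant-free cosine recipe, and seeded
#' training-set caps. All signal-processing, thresholding and fusion
#' parameters (windows, band, percentile, alpha, temporal vote) are
#' unchanged from [fd_config()].
#'
#' @param ... Overrides passed on to [fd_config()].
#' @return List of class `fd_config`.
#' @export
fd_config_small <- function(...) {
  defaults <- list(ae_hidden = 8, ae_lr = 1e-3, ae_epochs = 6,
                   ae_patience = 3, max_ae_windows = 600,
                   tf_d_model = 32, tf_layers = 1, tf_heads = 2,
                   tf_lr = 5e-3, tf_batch = 32, tf_epochs = 10,
                   tf_patience = 4, max_tf_segments = 500)
  over <- list(...)
  do.call(fd_config, utils::modifyList(defaults, over))
}

## Does [a1, a2] overlap the trial's fall event (if any)?
.fd_overlaps_event <- function(script, a1, a2, pad = 0) {
  if (is.null(script$event_interval)) return(FALSE)
  e <- script$event_interval
  a1 < e[2] + pad && a2 > e[1]
}

#' Fit the bimodal fall detector on a cohort
#'
#' Trains the inertial LSTM autoencoder on non-fall windows (band-passed and
#' z-scored with training-partition moments), calibrates the anomaly
#' threshold as the configured percentile of training reconstruction errors,
#' trains the pose Transformer on labeled 1-s segments, and initializes the
#' fusion head to the conjunctive threshold rule.
#'
#' @param cohort An [fd_generate_cohort()] cohort (or any list with the same
#'   structure).
#' @param subjects Subjects to train on (default: all in the cohort).
#' @param config An [fd_config()].
#' @param seed Integer seed.
#' @param verbose Progress messages.
#' @return Object of class `fall_detector`.
#' @export
fall_detector <- function(cohort, subjects = NULL, config = fd_config(),
                          seed = 1, verbose = FALSE) {
  if (is.null(subjects)) subjects <- cohort$subjects
  trials <- unlist(lapply(subjects, function(s) cohort$trials[[s]]),
                   recursive = FALSE)
  .fd_assert(length(trials) > 0, "no training trials")

  ## normalization moments from the training partition only
  zstats <- fd_train_stats(lapply(trials, function(tr) tr$imu[, -1]),
                           band = config$band, fs = config$fs,
                           order = config$filter_order)

  nonfall_windows <- list()
  segments <- list()
  seg_labels <- character()
  for (tr in trials) {
    pp <- fd_preprocess(tr$imu[, -1], band = config$band, fs = config$fs,
                        stats = zstats, order = config$filter_order)
    ws <- fd_make_windows(pp, config$window, config$overlap, t = tr$imu$t)
    for (w in ws) {
      if (!.fd_overlaps_event(tr$script, w$interval[1], w$interval[2],
                              config$event_pad)) {
        nonfall_windows[[length(nonfall_windows) + 1L]] <- w
      }
    }
    segs <- fd_pose_segments(tr$pose, config$frames_per_segment)
    for (sg in segs) {
      segments[[length(segments) + 1L]] <- sg
      ## vision training target is the fallen STATE (body horizontal at
      ## floor level), known per frame for simulated trials; trials read
      ## from disk fall back to event-interval overlap
      lab <- if (!is.null(tr$on_floor)) {
        if (mean(tr$on_floor[sg$frame_idx]) >= 0.5) "fallen" else "normal"
      } else if (.fd_overlaps_event(tr$script, sg$interval[1],
                                    sg$interval[2], config$event_pad)) {
        "fallen"
      } else "normal"
      seg_labels <- c(seg_labels, lab)
    }
  }
  .fd_assert(length(nonfall_windows) >= 2, "too few non-fall windows")

  if (is.finite(config$max_ae_windows) &&
      length(nonfall_windows) > config$max_ae_windows) {
    set.seed(fd_subseed(seed, 81L))
    keep <- sample(length(nonfall_windows), config$max_ae_windows)
    nonfall_windows <- nonfall_windows[keep]
  }
  if (is.finite(config$max_tf_segments) &&
      length(segments) > config$max_tf_segments) {
    ## stratified subsample: keep every fallen segment, thin the normals
    set.seed(fd_subseed(seed, 82L))
    pos <- which(seg_labels == "fallen")
    neg <- which(seg_labels == "normal")
    n_neg <- max(config$max_tf_segments - length(pos), length(pos))
    keep <- sort(c(pos, sample(neg, min(n_neg, length(neg)))))
    segments <- segments[keep]
    seg_labels <- seg_labels[keep]
  }

  if (verbose) message(sprintf("training AE on %d windows, TF on %d segments",
                               length(nonfall_windows), length(segments)))
  ae <- fd_autoencoder(hidden = config$ae_hidden, seed = seed)
  ae <- fd_train_autoencoder(ae, nonfall_windows, lr = config$ae_lr,
                             batch_size = config$ae_batch,
                             epochs = config$ae_epochs,
                             patience = config$ae_patience,
                             seed = fd_subseed(seed, 83L),
                             verbose = verbose)
  tau <- fd_calibrate_tau(ae$train_errors, config$tau_percentile)

  tf <- fd_transformer(d_model = config$tf_d_model,
                       n_layers = config$tf_layers,
                       n_heads = config$tf_heads,
                       seq_len = config$frames_per_segment, seed = seed)
  tf <- fd_train_transformer(tf, segments, seg_labels, lr = config$tf_lr,
                             batch_size = config$tf_batch,
                             epochs = config$tf_epochs,
                             patience = config$tf_patience,
                             schedule = config$tf_schedule,
                             seed = fd_subseed(seed, 84L),
                             verbose = verbose)

  head <- fd_fusion_head(alpha = config$alpha, seed = seed)
  structure(list(ae = ae, tau = tau, transformer = tf, head = head,
                 zstats = zstats, config = config, subjects = subjects,
                 seed = seed),
            class = "fall_detector")
}

#' @export
print.fall_detector <- function(x, ...) {
  cat("Bimodal fall detector\n")
  cat("  trained on:", length(x$subjects), "subjects\n")
  cat("  anomaly threshold tau =", format(x$tau$tau, digits = 4),
      sprintf("(%gth percentile of %d training errors)\n",
              x$tau$percentile, length(x$tau$calibration_errors)))
  cat("  fusion alpha =", x$config$alpha, "| vision mode:",
      x$config$vision_mode, "\n")
  print(x$ae)
  print(x$transformer)
  invisible(x)
}

#' @export
summary.fall_detector <- function(object, ...) {
  cat("Bimodal fall detector — training summary\n\n")
  print(object)
  cat("\nAE early stopping at epoch", object$ae$stopped_epoch,
      "| best val loss", format(min(object$ae$history$val), digits = 4), "\n")
  cat("TF early stopping at epoch", object$transformer$stopped_epoch,
      "| best val loss",
      format(min(object$transformer$history$val), digits = 4), "\n")
  invisible(object)
}

#' Per-epoch decisions for a trial
#'
#' Runs both branches on one trial and fuses them per 1-s decision epoch
#' (one epoch per pose segment): the IMU anomaly score paired with each
#' epoch is the maximum over windows centred within 0.6 s of the segment
#' centre; the vision probability is the (posture-gated) transformer
#' fallen-class probability.
#'
#' @param object A fitted [fall_detector()].
#' @param trial An `fd_trial`.
#' @param decision `"rule"` (default, conjunctive threshold rule) or
#'   `"head"` (fusion-head probability thresholded at 0.5).
#' @param ... Unused.
#' @return data.frame with one row per epoch: `epoch_start`, `epoch_end`,
#'   `p_fall`, `p_transformer`, `prone`, `s_anomaly`, `mse`, `label`,
#'   `truth`.
#' @export
predict.fall_detector <- function(object, trial, decision = c("rule", "head"),
                                  ...) {
  decision <- match.arg(decision)
  cfg <- object$config
  pp <- fd_preprocess(trial$imu[, -1], band = cfg$band, fs = cfg$fs,
                      stats = object$zstats, order = cfg$filter_order)
  ws <- fd_make_windows(pp, cfg$window, cfg$overlap, t = trial$imu$t)
  if (length(ws) > 0) {
    errs <- fd_reconstruction_errors(object$ae, ws)
    centers <- vapply(ws, function(w) w$center, numeric(1))
    scores <- fd_anomaly_score(errs, object$tau)$score
  } else {
    errs <- numeric(); centers <- numeric(); scores <- numeric()
  }
  flags <- fd_posture_flags(trial$pose, cfg$visibility_threshold)
  streak <- fd_prone_streak(flags, cfg$prone_required, cfg$occlusion_gap)
  segs <- fd_pose_segments(trial$pose, cfg$frames_per_segment)
  .fd_assert(length(segs) > 0, "trial too short for one pose segment")
  rows <- lapply(segs, function(sg) {
    prone_in <- any(streak$confirmed_frames[sg$frame_idx])
    vp <- fd_vision_probability(object$transformer, sg, prone_in,
                                mode = cfg$vision_mode,
                                attenuation = cfg$attenuation)
    data.frame(epoch_start = sg$interval[1], epoch_end = sg$interval[2],
               p_fall = vp$p_fall, p_transformer = vp$p_transformer,
               prone = prone_in)
  })
  out <- do.call(rbind, rows)
  seg_centers <- vapply(segs, function(sg) sg$center, numeric(1))
  s_pair <- fd_align_epochs(seg_centers, centers, scores, tol = 0.6)
  mse_pair <- fd_align_epochs(seg_centers, centers, errs, tol = 0.6)
  out$s_anomaly <- s_pair
  out$mse <- mse_pair
  fcfg <- fd_fusion_config(alpha = cfg$alpha)
  if (decision == "rule") {
    out$label <- fd_fuse(out$p_fall, out$s_anomaly, fcfg)
  } else {
    s_in <- ifelse(is.na(out$s_anomaly), 0, out$s_anomaly)
    ph <- fd_fusion_head_predict(object$head, out$p_fall, s_in)
    out$label <- ifelse(ph > 0.5, "FALL", "NORMAL")
    out$p_head <- ph
  }
  core <- fd_event_core(trial$script)
  out$truth <- if (is.null(core)) rep(FALSE, nrow(out)) else {
    out$epoch_start < core[2] + cfg$event_pad & out$epoch_end > core[1]
  }
  out
}

#' Confusion counts of epoch decisions
#'
#' Maps labels to binary FALL vs not-FALL (LOW_CONFIDENCE counts as
#' not-FALL by default — switchable) and tabulates against the epoch truth.
#'
#' @param decisions data.frame from [predict.fall_detector()] (or pooled
#'   rows thereof).
#' @param positive Labels counted as a positive (FALL) prediction.
#' @return List with `tp`, `fp`, `tn`, `fn`.
#' @export
fd_confusion <- function(decisions, positive = "FALL") {
  pred <- decisions$label %in% positive
  truth <- decisions$truth
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}
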