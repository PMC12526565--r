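## Synthetic multimodal cohort simulator.
##
## Emulates the acquisition protocol the detector is designed for: a
## waist-mounted 6-axis IMU (50 Hz, +/-16 g, +/-2000 deg/s) and a laterally
## placed RGB camera (30 fps, 1920x1080) whose frames have already been
## reduced to 33 normalized 2-D skeletal landmarks with visibility scores.
## Activities are piecewise kinematic templates chosen so that the detection
## cues the method relies on — an impulse-then-stillness acceleration
## signature and a postural transition of the landmark cloud from tall to
## wide — are present by construction.

.FD_ACTIVITIES <- c("fall_forward", "fall_backward", "fall_lateral",
                    "lie_down", "roll_over", "sit_up", "stand_up", "walk")
.FD_FALLS <- c("fall_forward", "fall_backward", "fall_lateral")
.FD_ADLS  <- c("lie_down", "roll_over", "sit_up", "stand_up", "walk")

#' Noise and nuisance-parameter configuration for the simulator
#'
#' Controls every stochastic nuisance the simulator injects: additive sensor
#' noise, landmark jitter, per-frame visibility dropouts (emulating sub-5-lux
#' occlusion), and the loose NTP-style clock offset between the two streams.
#'
#' @param accel_noise_sd Additive Gaussian noise on each accelerometer
#'   channel, in g.
#' @param gyro_noise_sd Additive Gaussian noise on each gyroscope channel,
#'   in deg/s.
#' @param landmark_jitter_sd Gaussian jitter on normalized landmark
#'   coordinates.
#' @param dropout_prob Per-landmark, per-frame probability that the landmark's
#'   visibility falls below the 0.5 usability threshold.
#' @param dropout_burst_prob Per-frame probability that a contiguous
#'   all-landmark occlusion burst begins.
#' @param dropout_burst_len Length of an occlusion burst, in frames.
#' @param clock_offset_max Bound on the constant per-stream start-time offset,
#'   in seconds (loose synchronization between IMU and camera clocks).
#' @param sample_jitter_sd Bounded per-sample timestamp noise, in seconds
#'   (truncated at +/- 2 sd; small relative to the sample spacing so
#'   timestamps stay strictly monotone).
#' @param impulse_peak_range Range (g) from which a fall's impact-peak
#'   acceleration is drawn uniformly before the per-subject impulse
#'   multiplier is applied.
#' @param adl_accel_cap Template cap (g) on the acceleration deviation from
#'   gravity that any ADL template may command (noise excluded).
#' @return A list of class `fd_noise_config`.
#' @export
fd_noise_config <- function(accel_noise_sd = 0.03,
                            gyro_noise_sd = 2,
                            landmark_jitter_sd = 0.004,
                            dropout_prob = 0.05,
                            dropout_burst_prob = 0,
                            dropout_burst_len = 8,
                            clock_offset_max = 0.1,
                            sample_jitter_sd = 0.002,
                            impulse_peak_range = c(2, 6),
                            adl_accel_cap = 1.5) {
  cfg <- list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
              landmark_jitter_sd = landmark_jitter_sd,
              dropout_prob = dropout_prob,
              dropout_burst_prob = dropout_burst_prob,
              dropout_burst_len = dropout_burst_len,
              clock_offset_max = clock_offset_max,
              sample_jitter_sd = sample_jitter_sd,
              impulse_peak_range = impulse_peak_range,
              adl_accel_cap = adl_accel_cap)
  class(cfg) <- "fd_noise_config"
  cfg
}

#' Script one activity trial
#'
#' @param activity_kind One of `"fall_forward"`, `"fall_backward"`,
#'   `"fall_lateral"`, `"lie_down"`, `"roll_over"`, `"sit_up"`,
#'   `"stand_up"`, `"walk"`.
#' @param duration Trial duration in seconds (>= 2).
#' @param event_interval For falls only: numeric `(start, end)` in seconds
#'   marking the fall event (descent onset through early post-impact rest).
#'   Defaults to a 3.5-s interval starting at 40% of the trial.
#' @param subject_params Per-subject kinematic modifiers: `stature` (scales
#'   the landmark cloud), `descent` (descent-speed multiplier), `impulse`
#'   (impact-magnitude multiplier).
#' @return An object of class `fd_script`.
#' @export
fd_script <- function(activity_kind, duration = 120, event_interval = NULL,
                      subject_params = list(stature = 1, descent = 1, impulse = 1)) {
  .fd_assert(activity_kind %in% .FD_ACTIVITIES,
             "unknown activity_kind '%s'", activity_kind)
  .fd_assert(is.numeric(duration) && duration >= 2,
             "duration must be >= 2 s (got %s)", format(duration))
  is_fall <- activity_kind %in% .FD_FALLS
  if (is_fall && is.null(event_interval)) {
    ## descent onset through impact plus ~1 s of early post-impact rest
    desc <- 0.8 / max(subject_params$descent, 0.2)
    e0 <- 0.4 * duration
    event_interval <- c(e0, min(e0 + desc + 1.2, duration))
  }
  if (!is_fall) {
    .fd_assert(is.null(event_interval),
               "event_interval is only valid for fall activities")
  } else {
    .fd_assert(length(event_interval) == 2 &&
                 event_interval[1] < event_interval[2],
               "event_interval must be an increasing (start, end) pair")
    .fd_assert(event_interval[1] >= 0 && event_interval[2] <= duration,
               "duration %.1f s too short to contain event_interval [%.1f, %.1f]",
               duration, event_interval[1], event_interval[2])
    .fd_assert(diff(event_interval) >= 1.5,
               "event_interval must span at least 1.5 s (descent + impact)")
  }
  structure(list(activity_kind = activity_kind, duration = duration,
                 event_interval = event_interval,
                 subject_params = subject_params),
            class = "fd_script")
}

## 33-landmark body template in body coordinates (u lateral, v longitudinal,
## v > 0 toward the head), roughly matching the proportions of a whole-body
## landmark set: dense head cluster, shoulders/arms, hips, legs.
fd_body_template <- function() {
  u <- c(0, -0.015, -0.025, -0.035, 0.015, 0.025, 0.035, -0.05, 0.05,
         -0.02, 0.02,                               # head (11)
         -0.06, 0.06, -0.075, 0.075, -0.08, 0.08,   # shoulders, elbows, wrists
         -0.085, 0.085, -0.08, 0.08, -0.075, 0.075, # hands
         -0.045, 0.045,                             # hips
         -0.05, 0.05,                               # knees
         -0.045, 0.045,                             # ankles
         -0.05, 0.05, -0.04, 0.04)                  # heels, foot tips
  v <- c(0.215, 0.22, 0.22, 0.22, 0.22, 0.22, 0.22, 0.21, 0.21,
         0.195, 0.195,
         0.15, 0.15, 0.05, 0.05, -0.03, -0.03,
         -0.05, -0.05, -0.055, -0.055, -0.05, -0.05,
         -0.02, -0.02,
         -0.12, -0.12,
         -0.205, -0.205,
         -0.215, -0.215, -0.22, -0.22)
  cbind(u = u, v = v)
}

## Piecewise-smooth ramp: 0 before t0, 1 after t1, smoothstep between.
.fd_ramp <- function(t, t0, t1) {
  s <- pmin(pmax((t - t0) / max(t1 - t0, 1e-9), 0), 1)
  s * s * (3 - 2 * s)
}

## Activity kinematics shared by both streams: body angle theta(t) (0 =
## upright, pi/2 = horizontal), body-centre path (cx, cy) in normalized image
## coordinates, and the acceleration deviation commanded by the template.
.fd_kinematics <- function(script, t, noise, peak_impulse) {
  kind <- script$activity_kind
  dur <- script$duration
  sp <- script$subject_params
  n <- length(t)
  theta <- numeric(n); cx <- rep(0.5, n); cy <- numeric(n)
  acc_dev <- matrix(0, n, 3)   # deviation from gravity, body axes (g)
  gyr_extra <- matrix(0, n, 3) # impulsive rotation (deg/s)

  if (kind %in% .FD_FALLS) {
    e0 <- script$event_interval[1]
    d_desc <- 0.8 / max(sp$descent, 0.2)
    t_imp <- e0 + d_desc
    r <- .fd_ramp(t, e0, t_imp)
    theta <- r * (pi / 2)
    cy <- 0.45 + r * (0.82 - 0.45)
    ## free-fall-like dip during descent, then impact impulse, then rest
    dip <- -0.6 * sin(pi * r)
    acc_dev[, 3] <- dip
    imp <- exp(-((t - t_imp)^2) / (2 * 0.03^2)) * peak_impulse
    dir3 <- switch(kind,
                   fall_forward  = c(0.8, 0.1, 0.59),
                   fall_backward = c(-0.8, 0.1, 0.59),
                   fall_lateral  = c(0.1, 0.8, 0.59))
    acc_dev <- acc_dev + outer(imp, dir3)
    gyr_extra[, 1] <- exp(-((t - t_imp)^2) / (2 * 0.05^2)) * 300
  } else if (kind == "lie_down") {
    t0 <- 0.3 * dur
    r <- .fd_ramp(t, t0, t0 + 3 / max(sp$descent, 0.2))
    theta <- r * (pi / 2)
    cy <- 0.45 + r * (0.55 - 0.45)
    acc_dev[, 3] <- -0.35 * sin(pi * r)
  } else if (kind == "roll_over") {
    theta[] <- pi / 2
    cy[] <- 0.55
    t0 <- 0.4 * dur
    r <- .fd_ramp(t, t0, t0 + 2)
    acc_dev[, 2] <- 0.4 * sin(pi * r)
    gyr_extra[, 1] <- 150 * sin(pi * r)
    cx <- 0.5 + 0.05 * r
  } else if (kind == "sit_up") {
    t0 <- 0.4 * dur
    r <- .fd_ramp(t, t0, t0 + 1.2)
    theta <- (1 - r) * (pi / 2)
    cy <- 0.55 - r * 0.07
    amp <- min(0.9 * sp$impulse, noise$adl_accel_cap)
    acc_dev[, 3] <- amp * sin(pi * .fd_ramp(t, t0, t0 + 0.5))^2 *
      exp(-((t - t0 - 0.3)^2) / (2 * 0.2^2))
    gyr_extra[, 2] <- 80 * sin(pi * r)
  } else if (kind == "stand_up") {
    t0 <- 0.35 * dur
    r <- .fd_ramp(t, t0, t0 + 2)
    theta <- (1 - r) * (pi / 2)
    cy <- 0.55 - r * (0.55 - 0.45)
    amp <- min(1.1 * sp$impulse, noise$adl_accel_cap)
    acc_dev[, 3] <- amp * exp(-((t - t0 - 1)^2) / (2 * 0.25^2))
    gyr_extra[, 2] <- 70 * sin(pi * r)
  } else if (kind == "walk") {
    theta[] <- 0
    cy[] <- 0.45
    cx <- 0.5 + 0.2 * sin(2 * pi * t / max(dur, 8))
    gait <- 0.35 * sin(2 * pi * 2 * t)
    acc_dev[, 3] <- gait
    acc_dev[, 1] <- 0.15 * sin(2 * pi * 2 * t + pi / 3)
    gyr_extra[, 3] <- 40 * sin(2 * pi * 2 * t)
  }
  list(theta = theta, cx = cx, cy = cy, acc_dev = acc_dev,
       gyr_extra = gyr_extra)
}

#' Generate one synthetic trial (synchronized IMU + landmark streams)
#'
#' Renders an [fd_script()] into a 50-Hz 6-axis IMU stream and a 30-fps
#' 33-landmark pose stream with the configured noise, visibility dropouts and
#' loose inter-stream clock offset. Identical `(script, noise, seed)` triples
#' produce identical trials.
#'
#' @param script An [fd_script()].
#' @param noise An [fd_noise_config()].
#' @param seed Integer seed.
#' @param subject_id Identifier stored with the trial.
#' @return An object of class `fd_trial` with elements `imu` (data.frame
#'   `t, ax, ay, az, gx, gy, gz`; g and deg/s), `pose` (list with `t`, an
#'   `n_frames x 33 x 3` array `lm` of `(x, y, visibility)`, and frame
#'   dimensions), `ground_truth` (per-second binary fall label) and `script`.
#' @export
fd_generate_trial <- function(script, noise = fd_noise_config(), seed,
                              subject_id = "S1") {
  .fd_assert(inherits(script, "fd_script"), "script must be an fd_script")
  .fd_assert(!missing(seed), "an explicit integer seed is required")
  set.seed(fd_subseed(seed, 11L))
  dur <- script$duration
  sp <- script$subject_params
  is_fall <- script$activity_kind %in% .FD_FALLS
  peak_impulse <- if (is_fall) {
    stats::runif(1, noise$impulse_peak_range[1], noise$impulse_peak_range[2]) *
      sp$impulse
  } else 0

  ## --- IMU stream (50 Hz) -------------------------------------------------
  n_imu <- round(dur * 50)
  off_imu <- stats::runif(1, -noise$clock_offset_max, noise$clock_offset_max)
  jit <- pmin(pmax(stats::rnorm(n_imu, 0, noise$sample_jitter_sd),
                   -2 * noise$sample_jitter_sd), 2 * noise$sample_jitter_sd)
  t_imu <- off_imu + (0:(n_imu - 1)) / 50 + jit
  t_nom <- (0:(n_imu - 1)) / 50
  kin <- .fd_kinematics(script, t_nom, noise, peak_impulse)
  ## gravity projected on body axes as the trunk rotates
  ax <- sin(kin$theta) + kin$acc_dev[, 1]
  ay <- kin$acc_dev[, 2]
  az <- cos(kin$theta) + kin$acc_dev[, 3]
  ## rotation rate from the angle trajectory (deg/s) plus impulsive terms
  dtheta <- c(diff(kin$theta), 0) * 50 * 180 / pi
  gx <- dtheta + kin$gyr_extra[, 1]
  gy <- kin$gyr_extra[, 2]
  gz <- kin$gyr_extra[, 3]
  acc <- cbind(ax, ay, az) +
    matrix(stats::rnorm(3 * n_imu, 0, noise$accel_noise_sd), n_imu, 3)
  gyr <- cbind(gx, gy, gz) +
    matrix(stats::rnorm(3 * n_imu, 0, noise$gyro_noise_sd), n_imu, 3)
  acc <- pmin(pmax(acc, -16), 16)
  gyr <- pmin(pmax(gyr, -2000), 2000)
  imu <- data.frame(t = t_imu, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                    gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3])

  ## --- Pose stream (30 fps) ----------------------------------------------
  n_pose <- round(dur * 30)
  off_pose <- stats::runif(1, -noise$clock_offset_max, noise$clock_offset_max)
  jitp <- pmin(pmax(stats::rnorm(n_pose, 0, noise$sample_jitter_sd),
                    -2 * noise$sample_jitter_sd), 2 * noise$sample_jitter_sd)
  t_pose <- off_pose + (0:(n_pose - 1)) / 30 + jitp
  t_nom_p <- (0:(n_pose - 1)) / 30
  kinp <- .fd_kinematics(script, t_nom_p, noise, peak_impulse)
  body <- fd_body_template() * sp$stature
  lm <- array(0, dim = c(n_pose, 33, 3))
  cth <- cos(kinp$theta); sth <- sin(kinp$theta)
  for (i in 1:33) {
    u <- body[i, 1]; v <- body[i, 2]
    x <- kinp$cx + u * cth + v * sth +
      stats::rnorm(n_pose, 0, noise$landmark_jitter_sd)
    y <- kinp$cy - v * cth + u * sth +
      stats::rnorm(n_pose, 0, noise$landmark_jitter_sd)
    lm[, i, 1] <- pmin(pmax(x, 0), 1)
    lm[, i, 2] <- pmin(pmax(y, 0), 1)
  }
  vis <- matrix(stats::runif(n_pose * 33, 0.75, 1), n_pose, 33)
  drop <- matrix(stats::runif(n_pose * 33) < noise$dropout_prob, n_pose, 33)
  if (noise$dropout_burst_prob > 0) {
    starts <- which(stats::runif(n_pose) < noise$dropout_burst_prob)
    for (s in starts) {
      idx <- s:min(s + noise$dropout_burst_len - 1, n_pose)
      drop[idx, ] <- TRUE
    }
  }
  vis[drop] <- stats::runif(sum(drop), 0, 0.45)
  lm[, , 3] <- vis
  pose <- list(t = t_pose, lm = lm, w_frame = 1920, h_frame = 1080)
  ## per-frame fallen-state indicator from the underlying kinematics: body
  ## horizontal AND at floor level (bed-height lying stays FALSE)
  on_floor <- kinp$theta > (pi / 4) & kinp$cy > 0.7

  ## --- Ground truth (per second) ------------------------------------------
  ## positive seconds are those overlapping the event core (the impact
  ## second), the unit a manual annotator would mark as "the fall"
  gt <- integer(ceiling(dur))
  if (is_fall) {
    e <- fd_event_core(script)
    secs <- 0:(length(gt) - 1)
    gt[secs < e[2] & (secs + 1) > e[1]] <- 1L
  }
  structure(list(subject_id = subject_id, script = script, imu = imu,
                 pose = pose, on_floor = on_floor, ground_truth = gt,
                 seed = seed),
            class = "fd_trial")
}

#' Generate a synthetic cohort
#'
#' Builds a cohort of scripted trials, half simulated falls (forward,
#' backward, lateral in rotation) and half routine activities (lying down,
#' rolling over, sitting up, standing up, walking in rotation), with
#' per-subject kinematic modifiers drawn once per subject to emulate
#' inter-individual variability. Defaults mirror the acquisition protocol
#' the detector targets: 16 subjects x 30 two-minute trials.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param trials_per_subject Trials per subject (even, for strict 50/50
#'   class balance).
#' @param seed Integer seed.
#' @param duration Trial duration in seconds.
#' @param noise An [fd_noise_config()].
#' @param balance `"strict"` (default; requires an even trial count) or
#'   `"none"`.
#' @return An object of class `fd_cohort`: list with `subjects`, `trials`
#'   (named list of per-subject trial lists) and `seed`.
#' @export
fd_generate_cohort <- function(n_subjects = 16, trials_per_subject = 30, seed,
                               duration = 120, noise = fd_noise_config(),
                               balance = c("strict", "none")) {
  balance <- match.arg(balance)
  .fd_assert(n_subjects >= 2, "a cohort needs at least 2 subjects")
  .fd_assert(!missing(seed), "an explicit integer seed is required")
  if (balance == "strict") {
    .fd_assert(trials_per_subject %% 2 == 0,
               "strict 50/50 balance requires an even trials_per_subject (got %d)",
               trials_per_subject)
  }
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  trials <- vector("list", n_subjects)
  names(trials) <- subjects
  for (s in seq_len(n_subjects)) {
    set.seed(fd_subseed(seed, 101L, s))
    sp <- list(stature = max(stats::rnorm(1, 1, 0.05), 0.8),
               descent = max(stats::rnorm(1, 1, 0.10), 0.5),
               impulse = max(stats::rnorm(1, 1, 0.15), 0.5))
    n_fall <- trials_per_subject %/% 2
    n_adl <- trials_per_subject - n_fall
    kinds <- c(rep_len(.FD_FALLS, n_fall), rep_len(.FD_ADLS, n_adl))
    subj_trials <- vector("list", trials_per_subject)
    for (k in seq_along(kinds)) {
      set.seed(fd_subseed(seed, 101L, s, k))
      ev <- NULL
      if (kinds[k] %in% .FD_FALLS) {
        e0 <- stats::runif(1, 0.25 * duration, max(0.25 * duration,
                                                   duration - 5))
        desc <- 0.8 / max(sp$descent, 0.2)
        ev <- c(e0, min(e0 + desc + 1.2, duration))
      }
      scr <- fd_script(kinds[k], duration = duration, event_interval = ev,
                       subject_params = sp)
      subj_trials[[k]] <- fd_generate_trial(
        scr, noise = noise, seed = fd_subseed(seed, 997L, s, k),
        subject_id = subjects[s])
    }
    trials[[s]] <- subj_trials
  }
  structure(list(subjects = subjects, trials = trials, seed = seed,
                 noise = noise),
            class = "fd_cohort")
}

#' @export
print.fd_cohort <- function(x, ...) {
  nt <- sum(vapply(x$trials, length, 1L))
  nf <- sum(vapply(x$trials, function(tr) {
    sum(vapply(tr, function(z) z$script$activity_kind %in% .FD_FALLS, TRUE))
  }, 1L))
  cat("Synthetic multimodal cohort:", length(x$subjects), "subjects,",
      nt, "trials (", nf, "falls /", nt - nf, "ADLs ), seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.fd_trial <- function(x, ...) {
  cat("Trial:", x$script$activity_kind, "| subject", x$subject_id,
      "|", x$script$duration, "s |", nrow(x$imu), "IMU samples,",
      dim(x$pose$lm)[1], "pose frames\n")
  invisible(x)
}

## TRUE for fall trials.
fd_is_fall_trial <- function(trial) {
  trial$script$activity_kind %in% .FD_FALLS
}

#' Core interval of a scripted fall event
#'
#' The scripted `event_interval` spans the whole fall phase (descent onset
#' through early rest); the event CORE is the second surrounding the impact
#' itself — the unit annotators mark and detectors are expected to flag.
#' Defined as impact time minus 0.4 s to impact plus 1.0 s, clipped to the
#' trial.
#'
#' @param script An [fd_script()].
#' @return `(start, end)` in seconds, or `NULL` for non-fall scripts.
#' @export
fd_event_core <- function(script) {
  if (is.null(script$event_interval)) return(NULL)
  desc <- 0.8 / max(script$subject_params$descent, 0.2)
  imp <- script$event_interval[1] + desc
  c(max(imp - 0.4, 0), min(imp + 1.0, script$duration))
}
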