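## Shared fixtures: everything is generated in code at test time.

## Tiny cohort for pipeline tests: 2 subjects x 4 trials of 10 s.
tiny_cohort <- function(seed = 7, n_subjects = 2, trials = 4, duration = 10) {
  fd_generate_cohort(n_subjects, trials, seed = seed, duration = duration)
}

## Reduced config for pipeline tests (even smaller than fd_config_small).
tiny_config <- function(...) {
  fd_config_small(ae_epochs = 4, ae_patience = 2, max_ae_windows = 200,
                  tf_epochs = 6, tf_patience = 3, max_tf_segments = 200, ...)
}

## Noise-free generator settings (template signal only).
quiet_noise <- function(...) {
  fd_noise_config(accel_noise_sd = 0, gyro_noise_sd = 0,
                  landmark_jitter_sd = 0, dropout_prob = 0,
                  clock_offset_max = 0, sample_jitter_sd = 0, ...)
}

## Synthetic pose-segment features for transformer tests: class 1 is a
## wide/low landmark cloud, class 2 tall/high, plus jitter.
fake_segments <- function(n_per_class, seed = 1, sd = 0.02) {
  set.seed(seed)
  mk <- function(wide) {
    cx <- 0.5; cy <- if (wide) 0.8 else 0.45
    u <- seq(-0.2, 0.2, length.out = 33)
    x <- if (wide) cx + u else cx + u * 0.3
    y <- if (wide) cy + u * 0.3 else cy + u
    feat <- matrix(0, 30, 66)
    feat[, seq(1, 66, 2)] <- matrix(rep(x, each = 30), 30) +
      matrix(rnorm(30 * 33, 0, sd), 30)
    feat[, seq(2, 66, 2)] <- matrix(rep(y, each = 30), 30) +
      matrix(rnorm(30 * 33, 0, sd), 30)
    list(features = feat)
  }
  segs <- c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
            lapply(seq_len(n_per_class), function(i) mk(FALSE)))
  labels <- rep(c("fallen", "normal"), each = n_per_class)
  list(segments = segs, labels = labels)
}
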