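## IMU preprocessing and windowing.

## Zero-phase filtering with mean removal and odd-reflection padding: the
## raw filter starts from zero state, so an unpadded signal with nonzero
## mean rings at both edges for seconds at a 0.2 Hz corner. Demeaning plus
## reflecting ~5 s of signal around each endpoint (the standard remedy)
## confines the transient to the discarded pad.
.fd_filtfilt <- function(bf, ch, pad = 250) {
  n <- length(ch)
  p <- min(pad, n - 1)
  mu <- mean(ch)
  x <- ch - mu
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)]
}

#' Band-pass filter and z-score a 6-channel IMU series
#'
#' Applies a 4th-order Butterworth band-pass (default 0.2-20 Hz at 50 Hz
#' sampling) with zero-phase forward-backward filtering, then z-scores each
#' channel. Filtering comes first: z-scoring a raw channel would be undone by
#' the filter's DC rejection, so normalization is applied to the filtered
#' signal. When `stats` (training-partition moments) is supplied it is used
#' for the z-score so that test data never contributes to normalization;
#' otherwise the series' own moments are used.
#'
#' @param x Numeric matrix or data.frame, samples x 6 channels
#'   (`ax, ay, az, gx, gy, gz`).
#' @param band Band-pass corner frequencies in Hz, `c(low, high)`.
#' @param fs Sampling rate in Hz.
#' @param stats Optional list with `mean` and `sd` vectors of length 6.
#' @param order Butterworth design order (the zero-phase pass doubles the
#'   effective order).
#' @return Matrix of the same dimension; attribute `"stats"` carries the
#'   moments used.
#' @export
fd_preprocess <- function(x, band = c(0.2, 20), fs = 50, stats = NULL,
                          order = 4) {
  x <- as.matrix(x)
  .fd_assert(ncol(x) == 6, "expected 6 channels, got %d", ncol(x))
  .fd_assert(band[2] < fs / 2,
             "high cutoff %.1f Hz must be below Nyquist (%.1f Hz)",
             band[2], fs / 2)
  nmin <- 3 * (2 * order + 1)
  .fd_assert(nrow(x) >= nmin,
             "series too short for zero-phase filtering (%d < %d samples)",
             nrow(x), nmin)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt <- apply(x, 2, function(ch) .fd_filtfilt(bf, ch))
  if (is.null(stats)) {
    mu <- colMeans(filt)
    sdv <- apply(filt, 2, stats::sd)
  } else {
    mu <- stats$mean
    sdv <- stats$sd
  }
  zero_var <- which(sdv < 1e-12)
  if (length(zero_var) > 0) {
    stop(sprintf("zero-variance channel(s): %s",
                 paste(zero_var, collapse = ", ")), call. = FALSE)
  }
  out <- sweep(sweep(filt, 2, mu, "-"), 2, sdv, "/")
  colnames(out) <- colnames(x)
  attr(out, "stats") <- list(mean = mu, sd = sdv)
  out
}

#' Pooled per-channel moments of filtered training data
#'
#' Computes the band-passed per-channel mean and sd over a list of raw series,
#' for reuse as the `stats` argument of [fd_preprocess()] at test time.
#'
#' @param series_list List of samples x 6 matrices (raw units).
#' @inheritParams fd_preprocess
#' @return List with `mean` and `sd` (length-6 vectors).
#' @export
fd_train_stats <- function(series_list, band = c(0.2, 20), fs = 50,
                           order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt <- lapply(series_list, function(x) {
    apply(as.matrix(x), 2, function(ch) .fd_filtfilt(bf, ch))
  })
  all <- do.call(rbind, filt)
  list(mean = colMeans(all), sd = apply(all, 2, stats::sd))
}

#' Segment a series into fixed-length overlapping windows
#'
#' Windows of `window` samples with fractional `overlap` start at
#' 0, `window*(1-overlap)`, ... Only complete windows are emitted; a series
#' shorter than one window yields an empty list. With the defaults (60
#' samples, 50% overlap at 50 Hz) each window spans 1.2 s and starts every
#' 0.6 s.
#'
#' @param x Samples x channels matrix (typically the output of
#'   [fd_preprocess()]).
#' @param window Window length in samples.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @param t Optional per-sample timestamps; if given, each window records its
#'   source interval and centre time.
#' @return List of windows; each is a list with `samples` (window x channels
#'   matrix), `index`, `start` (0-based sample offset) and, when `t` is
#'   given, `interval` and `center` in seconds.
#' @export
fd_make_windows <- function(x, window = 60, overlap = 0.5, t = NULL) {
  x <- as.matrix(x)
  .fd_assert(window >= 2, "window must be >= 2 samples")
  .fd_assert(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  n <- nrow(x)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  if (n < window) return(list())
  starts <- seq(0L, n - window, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    w <- list(index = i, start = s,
              samples = x[(s + 1L):(s + window), , drop = FALSE])
    if (!is.null(t)) {
      w$interval <- c(t[s + 1L], t[s + window])
      w$center <- (t[s + 1L] + t[s + window]) / 2
    }
    w
  })
}
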