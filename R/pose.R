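## Landmark geometry: pixel conversion, visibility-filtered bounding box,
## aspect-ratio posture cue, and the 30-frame temporal vote (prone streak).

#' Convert normalized landmark coordinates to pixels
#'
#' @param x_norm,y_norm Normalized coordinates in `[0, 1]` (vectorized).
#' @param w_frame,h_frame Frame dimensions in pixels (positive).
#' @return List with `x_pixel`, `y_pixel` (real-valued; no rounding).
#' @export
fd_to_pixels <- function(x_norm, y_norm, w_frame, h_frame) {
  .fd_assert(w_frame > 0 && h_frame > 0,
             "frame dimensions must be positive (got %s x %s)",
             format(w_frame), format(h_frame))
  list(x_pixel = x_norm * w_frame, y_pixel = y_norm * h_frame)
}

#' Bounding box of the visible landmarks
#'
#' Min/max pixel coordinates over the landmarks whose visibility is strictly
#' greater than the threshold (default 0.5). Fewer than two usable landmarks
#' leave the box undefined and the frame flagged occluded.
#'
#' @param landmarks 33 x 3 matrix of `(x_norm, y_norm, visibility)`.
#' @param w_frame,h_frame Frame dimensions in pixels.
#' @param visibility_threshold Strict lower visibility bound.
#' @return List with `x_min`, `x_max`, `y_min`, `y_max`, `n_visible`,
#'   `occluded`.
#' @export
fd_bounding_box <- function(landmarks, w_frame = 1920, h_frame = 1080,
                            visibility_threshold = 0.5) {
  landmarks <- as.matrix(landmarks)
  .fd_assert(ncol(landmarks) == 3, "landmarks must have 3 columns")
  keep <- landmarks[, 3] > visibility_threshold
  if (sum(keep) < 2) {
    return(list(x_min = NA_real_, x_max = NA_real_, y_min = NA_real_,
                y_max = NA_real_, n_visible = sum(keep), occluded = TRUE))
  }
  px <- fd_to_pixels(landmarks[keep, 1], landmarks[keep, 2], w_frame, h_frame)
  list(x_min = min(px$x_pixel), x_max = max(px$x_pixel),
       y_min = min(px$y_pixel), y_max = max(px$y_pixel),
       n_visible = sum(keep), occluded = FALSE)
}

#' Bounding-box aspect ratio and posture flag
#'
#' `rho = width / height`; `rho > 1` (strict) flags a prone or horizontal
#' posture, `rho <= 1` upright. A degenerate box (zero height or occluded
#' frame) leaves the posture undefined.
#'
#' @param box Output of [fd_bounding_box()].
#' @return List with `rho` and `posture` (`"prone"`, `"upright"` or
#'   `"occluded"`).
#' @export
fd_aspect_ratio <- function(box) {
  if (isTRUE(box$occluded)) {
    return(list(rho = NA_real_, posture = "occluded"))
  }
  h <- box$y_max - box$y_min
  if (h <= 0) return(list(rho = NA_real_, posture = "occluded"))
  rho <- (box$x_max - box$x_min) / h
  list(rho = rho, posture = if (rho > 1) "prone" else "upright")
}

#' Per-frame posture flags of a pose stream
#'
#' @param pose Pose stream (list with `lm` array `n x 33 x 3`, `w_frame`,
#'   `h_frame`), as produced by the simulator or [fd_read_pose_jsonl()].
#' @param visibility_threshold Strict landmark visibility bound.
#' @return Character vector (`"prone"`, `"upright"`, `"occluded"`), one
#'   per frame.
#' @export
fd_posture_flags <- function(pose, visibility_threshold = 0.5) {
  n <- dim(pose$lm)[1]
  vapply(seq_len(n), function(i) {
    box <- fd_bounding_box(pose$lm[i, , ], pose$w_frame, pose$h_frame,
                           visibility_threshold)
    fd_aspect_ratio(box)$posture
  }, character(1))
}

#' Temporal vote over posture flags (prone streak)
#'
#' Confirms a fall posture when at least `required` strictly adjacent prone
#' frames occur (1 s at 30 fps by default). Any upright or occluded frame
#' resets the run, except that up to `occlusion_gap` consecutive occluded
#' frames inside a run may be tolerated (default 0: strict adjacency).
#'
#' @param flags Character vector of per-frame flags from
#'   [fd_posture_flags()].
#' @param required Run length needed for confirmation.
#' @param occlusion_gap Number of consecutive occluded (not upright) frames
#'   tolerated without resetting the run; tolerated occluded frames do not
#'   count toward the run length.
#' @return List with `confirmed`, `streak_length` (longest run), and
#'   `confirmed_frames` (logical per frame: frame belongs to a confirming
#'   run).
#' @export
fd_prone_streak <- function(flags, required = 30, occlusion_gap = 0) {
  .fd_assert(required >= 1, "required streak must be >= 1")
  n <- length(flags)
  confirmed_frames <- logical(n)
  if (n == 0) {
    return(list(confirmed = FALSE, streak_length = 0L,
                confirmed_frames = confirmed_frames))
  }
  best <- 0L
  run <- 0L; gap <- 0L; run_start <- NA_integer_
  flush <- function(run, run_start, i_end) {
    if (run >= required && run > 0) {
      confirmed_frames[run_start:i_end] <<- TRUE
    }
  }
  for (i in seq_len(n)) {
    f <- flags[i]
    if (f == "prone") {
      if (run == 0L) run_start <- i
      run <- run + 1L
      gap <- 0L
    } else if (f == "occluded" && run > 0L && gap < occlusion_gap) {
      gap <- gap + 1L
    } else {
      flush(run, run_start, i - 1L - gap)
      run <- 0L; gap <- 0L
    }
    best <- max(best, run)
  }
  flush(run, run_start, n)
  list(confirmed = best >= required, streak_length = as.integer(best),
       confirmed_frames = confirmed_frames)
}

#' Tile a pose stream into 1-s classification segments
#'
#' Consecutive non-overlapping blocks of `frames_per_segment` frames; a
#' trailing incomplete block is dropped. Each segment carries the flattened
#' 30 x 66 feature matrix of normalized coordinates (x then y per landmark).
#'
#' @param pose Pose stream (see [fd_posture_flags()]).
#' @param frames_per_segment Frames per segment (default 30; 1 s at 30 fps).
#' @return List of segments: `features` (frames x 66), `frame_idx`,
#'   `interval` `(t_start, t_end)`, `center`.
#' @export
fd_pose_segments <- function(pose, frames_per_segment = 30) {
  n <- dim(pose$lm)[1]
  k <- n %/% frames_per_segment
  if (k == 0) return(list())
  lapply(seq_len(k), function(j) {
    idx <- ((j - 1) * frames_per_segment + 1):(j * frames_per_segment)
    xy <- pose$lm[idx, , 1:2, drop = FALSE]
    ## interleave x, y per landmark: columns (x1, y1, x2, y2, ...)
    feat <- matrix(0, frames_per_segment, 66)
    feat[, seq(1, 66, by = 2)] <- xy[, , 1]
    feat[, seq(2, 66, by = 2)] <- xy[, , 2]
    list(features = feat, frame_idx = idx,
         interval = c(pose$t[idx[1]], pose$t[idx[length(idx)]]),
         center = (pose$t[idx[1]] + pose$t[idx[length(idx)]]) / 2)
  })
}
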