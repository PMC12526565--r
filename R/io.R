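## Readers and writers for the package's plain-text stream formats:
## IMU CSV (t,ax,ay,az,gx,gy,gz; g and deg/s), pose line-delimited JSON
## ({"t": ..., "landmarks": [[x, y, visibility] x 33]}), cohort manifests and
## run configurations as JSON.

#' Write an IMU stream to CSV
#'
#' @param imu data.frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param path Output file.
#' @export
fd_write_imu_csv <- function(imu, path) {
  .fd_assert(identical(names(imu), c("t", "ax", "ay", "az", "gx", "gy", "gz")),
             "imu must have columns t,ax,ay,az,gx,gy,gz")
  utils::write.csv(imu, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IMU stream from CSV
#'
#' Enforces the column layout, strictly increasing timestamps and the
#' sensor's physical ranges (+/-16 g, +/-2000 deg/s); violations are
#' rejected with the first offending row number. Sampling gaps (over 3x the
#' median spacing) are reported as an attribute.
#'
#' @param path CSV file with header `t,ax,ay,az,gx,gy,gz`.
#' @return data.frame of samples; attribute `"gaps"` lists gap row indices.
#' @export
fd_read_imu_csv <- function(path) {
  d <- utils::read.csv(path)
  .fd_assert(identical(names(d), c("t", "ax", "ay", "az", "gx", "gy", "gz")),
             "bad header in %s: expected t,ax,ay,az,gx,gy,gz", path)
  if (nrow(d) > 1) {
    bad <- which(diff(d$t) <= 0)
    .fd_assert(length(bad) == 0,
               "non-monotone timestamps at row %d of %s",
               if (length(bad) > 0) bad[1] + 1L else 0L, path)
  }
  acc <- as.matrix(d[, c("ax", "ay", "az")])
  bad_a <- which(rowSums(abs(acc) > 16) > 0)
  .fd_assert(length(bad_a) == 0,
             "acceleration out of sensor range (+/-16 g) at row %d",
             if (length(bad_a) > 0) bad_a[1] else 0L)
  gyr <- as.matrix(d[, c("gx", "gy", "gz")])
  bad_g <- which(rowSums(abs(gyr) > 2000) > 0)
  .fd_assert(length(bad_g) == 0,
             "angular velocity out of sensor range (+/-2000 deg/s) at row %d",
             if (length(bad_g) > 0) bad_g[1] else 0L)
  if (nrow(d) > 2) {
    dt <- diff(d$t)
    attr(d, "gaps") <- which(dt > 3 * stats::median(dt))
  }
  d
}

#' Write a pose stream as line-delimited JSON
#'
#' One record per frame: `{"t": ..., "landmarks": [[x, y, visibility] x 33]}`.
#'
#' @param pose Pose stream (list with `t`, `lm`, `w_frame`, `h_frame`).
#' @param path Output file.
#' @export
fd_write_pose_jsonl <- function(pose, path) {
  n <- dim(pose$lm)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    rec <- list(t = pose$t[i],
                landmarks = unname(lapply(1:33, function(j) {
                  as.numeric(pose$lm[i, j, ])
                })))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a pose stream from line-delimited JSON
#'
#' Validates 33 landmarks per frame and all coordinate/visibility ranges;
#' violations are rejected with the offending line number. The estimated
#' frame rate is attached as an attribute.
#'
#' @param path JSONL file.
#' @param w_frame,h_frame Frame dimensions to associate with the stream.
#' @return Pose stream list (`t`, `lm`, `w_frame`, `h_frame`).
#' @export
fd_read_pose_jsonl <- function(path, w_frame = 1920, h_frame = 1080) {
  lines <- readLines(path)
  .fd_assert(length(lines) > 0, "empty pose file %s", path)
  n <- length(lines)
  t <- numeric(n)
  lm <- array(0, c(n, 33, 3))
  for (i in seq_len(n)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyMatrix = TRUE)
    lmk <- rec$landmarks
    .fd_assert(is.matrix(lmk) && nrow(lmk) == 33 && ncol(lmk) == 3,
               "line %d of %s: expected 33 [x, y, visibility] landmarks",
               i, path)
    .fd_assert(all(lmk >= 0) && all(lmk <= 1),
               "line %d of %s: landmark value outside [0, 1]", i, path)
    t[i] <- rec$t
    lm[i, , ] <- lmk
  }
  pose <- list(t = t, lm = lm, w_frame = w_frame, h_frame = h_frame)
  if (n > 1) attr(pose, "fps_estimate") <- 1 / stats::median(diff(t))
  pose
}

#' Write a cohort to disk (streams + manifest)
#'
#' Writes each trial's IMU CSV and pose JSONL plus a single JSON manifest
#' pairing the files with subject ids, activity labels, event intervals and
#' the generator seed.
#'
#' @param cohort An [fd_generate_cohort()] cohort.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
fd_write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cohort$seed, subjects = cohort$subjects,
                   trials = list())
  for (s in cohort$subjects) {
    for (k in seq_along(cohort$trials[[s]])) {
      tr <- cohort$trials[[s]][[k]]
      base <- sprintf("%s_trial%02d", s, k)
      fd_write_imu_csv(tr$imu, file.path(dir, paste0(base, "_imu.csv")))
      fd_write_pose_jsonl(tr$pose, file.path(dir, paste0(base, "_pose.jsonl")))
      manifest$trials[[base]] <- list(
        subject = s, activity = tr$script$activity_kind,
        duration = tr$script$duration,
        event_interval = tr$script$event_interval,
        imu = paste0(base, "_imu.csv"), pose = paste0(base, "_pose.jsonl"))
    }
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mp)
}

#' Serialize / restore a run configuration
#'
#' JSON round-trip of an [fd_config()]; every default equals the reference
#' operating point, so a freshly written and re-read config reproduces it
#' losslessly.
#'
#' @param config An [fd_config()].
#' @param path JSON file.
#' @export
fd_write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname fd_write_config
#' @export
fd_read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cfg <- fd_config()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    ## JSON has no Inf literal; numeric fields come back as strings
    if (is.numeric(cfg[[nm]]) && is.character(v)) v <- as.numeric(v)
    cfg[[nm]] <- v
  }
  class(cfg) <- "fd_config"
  cfg
}
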