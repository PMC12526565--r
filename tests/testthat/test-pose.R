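test_that("normalized-to-pixel conversion is exact and unrounded", {
  expect_equal(fd_to_pixels(0.5, 0.5, 1920, 1080),
               list(x_pixel = 960, y_pixel = 540))
  expect_equal(fd_to_pixels(0, 0, 640, 480), list(x_pixel = 0, y_pixel = 0))
  expect_equal(fd_to_pixels(0.25, 0.8, 640, 480),
               list(x_pixel = 160, y_pixel = 384))
  expect_error(fd_to_pixels(0.5, 0.5, 0, 1080), "positive")
})

test_that("bounding box takes min/max over sufficiently visible landmarks", {
  lm <- matrix(0, 33, 3)
  lm[1, ] <- c(10, 20, 0.9)
  lm[2, ] <- c(30, 5, 0.8)
  lm[3, ] <- c(15, 40, 0.7)
  lm[4:33, 3] <- 0   # invisible
  box <- fd_bounding_box(lm, w_frame = 1, h_frame = 1)
  expect_equal(c(box$x_min, box$x_max, box$y_min, box$y_max),
               c(10, 30, 5, 40))
  expect_equal(box$n_visible, 3)

  ## a low-visibility outlier is excluded
  lm[4, ] <- c(1000, 1000, 0.4)
  box <- fd_bounding_box(lm, w_frame = 1, h_frame = 1)
  expect_equal(box$x_max, 30)

  ## visibility exactly at the threshold is excluded (strict >)
  lm[4, ] <- c(1000, 1000, 0.5)
  expect_equal(fd_bounding_box(lm, 1, 1)$x_max, 30)

  lm[, 3] <- 0
  expect_true(fd_bounding_box(lm, 1, 1)$occluded)
})

test_that("bounding box equals a brute-force oracle on random frames", {
  set.seed(51)
  for (rep in 1:20) {
    lm <- cbind(runif(33), runif(33), runif(33))
    box <- fd_bounding_box(lm, 1920, 1080)
    keep <- lm[, 3] > 0.5
    if (sum(keep) < 2) {
      expect_true(box$occluded)
    } else {
      expect_equal(box$x_min, min(lm[keep, 1] * 1920))
      expect_equal(box$x_max, max(lm[keep, 1] * 1920))
      expect_equal(box$y_min, min(lm[keep, 2] * 1080))
      expect_equal(box$y_max, max(lm[keep, 2] * 1080))
    }
  }
})

test_that("aspect ratio and the strict prone rule behave at the boundary", {
  mkbox <- function(w, h) list(x_min = 0, x_max = w, y_min = 0, y_max = h,
                               occluded = FALSE)
  r <- fd_aspect_ratio(mkbox(30, 10))
  expect_equal(r$rho, 3)
  expect_equal(r$posture, "prone")
  r <- fd_aspect_ratio(mkbox(20, 35))
  expect_equal(r$rho, 20 / 35)
  expect_equal(r$posture, "upright")
  ## rho == 1 exactly is NOT prone
  expect_equal(fd_aspect_ratio(mkbox(25, 25))$posture, "upright")
  expect_equal(fd_aspect_ratio(mkbox(25, 0))$posture, "occluded")
})

test_that("aspect ratio is invariant to translation and uniform scaling", {
  set.seed(52)
  lm <- cbind(runif(33, 0.2, 0.6), runif(33, 0.2, 0.6), runif(33, 0.6, 1))
  rho0 <- fd_aspect_ratio(fd_bounding_box(lm, 1000, 1000))$rho
  lm_shift <- lm; lm_shift[, 1:2] <- lm[, 1:2] + 0.3
  expect_equal(fd_aspect_ratio(fd_bounding_box(lm_shift, 1000, 1000))$rho,
               rho0, tolerance = 1e-12)
  expect_equal(fd_aspect_ratio(fd_bounding_box(lm, 3000, 3000))$rho,
               rho0, tolerance = 1e-12)
})

test_that("prone streak requires strict adjacency", {
  expect_true(fd_prone_streak(rep("prone", 30))$confirmed)
  expect_false(fd_prone_streak(rep("prone", 29))$confirmed)
  broken <- c(rep("prone", 29), "upright", rep("prone", 29))
  expect_false(fd_prone_streak(broken)$confirmed)
  ## one occluded frame splits 100 prone frames into runs of 49 and 50
  occl <- rep("prone", 100); occl[50] <- "occluded"
  st <- fd_prone_streak(occl)
  expect_true(st$confirmed)
  expect_equal(st$streak_length, 50L)
  expect_false(fd_prone_streak(character(0))$confirmed)
})

test_that("occlusion-gap tolerance bridges short dropouts only", {
  flags <- c(rep("prone", 20), "occluded", rep("prone", 15))
  expect_false(fd_prone_streak(flags, required = 30)$confirmed)
  expect_true(fd_prone_streak(flags, required = 30,
                              occlusion_gap = 1)$confirmed)
  ## upright frames always reset, whatever the gap
  flags[21] <- "upright"
  expect_false(fd_prone_streak(flags, required = 30,
                               occlusion_gap = 5)$confirmed)
})

test_that("prone streak matches a run-length-encoding oracle", {
  set.seed(53)
  for (rep in 1:40) {
    flags <- sample(c("prone", "upright", "occluded"), 80, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2))
    req <- sample(2:20, 1)
    r <- rle(flags == "prone")
    runs <- r$lengths[r$values]
    best <- if (length(runs) > 0) max(runs) else 0L
    st <- fd_prone_streak(flags, required = req)
    expect_equal(st$streak_length, as.integer(best))
    expect_equal(st$confirmed, best >= req)
  }
})

test_that("pose segments tile the stream without overlap", {
  tr <- fd_generate_trial(fd_script("walk", duration = 10),
                          noise = quiet_noise(), seed = 54)
  segs <- fd_pose_segments(tr$pose)
  expect_length(segs, 10)           # 300 frames / 30
  expect_equal(dim(segs[[1]]$features), c(30, 66))
  idx <- unlist(lapply(segs, function(s) s$frame_idx))
  expect_equal(idx, 1:300)          # contiguous, no overlap
  ## 45 frames give one segment; the incomplete tail is dropped
  short <- tr$pose
  short$lm <- short$lm[1:45, , , drop = FALSE]
  short$t <- short$t[1:45]
  expect_length(fd_pose_segments(short), 1)
  ## feature columns interleave x and y of each landmark
  expect_equal(segs[[1]]$features[1, 1], tr$pose$lm[1, 1, 1])
  expect_equal(segs[[1]]$features[1, 2], tr$pose$lm[1, 1, 2])
})
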