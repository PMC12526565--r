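test_that("nominal stream lengths match the sampling rates", {
  scr <- fd_script("fall_forward", duration = 120)
  tr <- fd_generate_trial(scr, noise = quiet_noise(), seed = 1)
  expect_equal(nrow(tr$imu), 120 * 50)
  expect_equal(dim(tr$pose$lm), c(120 * 30, 33, 3))
  ## zero clock jitter: timestamps are the nominal grids
  expect_equal(tr$imu$t, (0:5999) / 50)
  expect_equal(tr$pose$t, (0:3599) / 30)
})

test_that("walking trials carry no event and stay under the ADL cap", {
  tr <- fd_generate_trial(fd_script("walk", duration = 10),
                          noise = quiet_noise(), seed = 2)
  expect_true(all(tr$ground_truth == 0))
  cap <- quiet_noise()$adl_accel_cap
  expect_lt(max(abs(as.matrix(tr$imu[, 2:4]))), 1 + cap)
})

test_that("fall impact magnitude follows the configured template peak", {
  nz <- quiet_noise(impulse_peak_range = c(4, 4))
  scr <- fd_script("fall_lateral", duration = 12,
                   subject_params = list(stature = 1, descent = 1,
                                         impulse = 1))
  tr <- fd_generate_trial(scr, noise = nz, seed = 3)
  ## brute-force scan of all samples inside the scripted event
  ev <- scr$event_interval
  acc <- as.matrix(tr$imu[, 2:4])
  mag <- sqrt(rowSums(acc^2))
  inside <- tr$imu$t >= ev[1] & tr$imu$t <= ev[2]
  peak <- max(mag[inside])
  ## the commanded impulse peaks at 4 g along a unit direction, superposed
  ## on the <=1 g gravity projection
  expect_gte(peak, 4)
  expect_lte(peak, 5.1)
  expect_equal(max(mag), peak)  # the global peak lies inside the event
})

test_that("event intervals are validated against the trial duration", {
  expect_error(fd_script("fall_forward", duration = 3,
                         event_interval = c(1, 5)),
               "too short")
  expect_error(fd_script("walk", duration = 10, event_interval = c(1, 3)),
               "only valid for fall")
  expect_error(fd_script("fall_forward", duration = 1), ">= 2 s")
})

test_that("cohort structure, class balance and determinism hold", {
  coh <- fd_generate_cohort(4, 10, seed = 5, duration = 8)
  expect_length(coh$subjects, 4)
  expect_equal(sum(lengths(coh$trials)), 40)
  n_fall <- sum(vapply(unlist(coh$trials, recursive = FALSE),
                       fallfuse:::fd_is_fall_trial, TRUE))
  expect_equal(n_fall, 20)
  expect_error(fd_generate_cohort(2, 3, seed = 1, duration = 8),
               "even trials_per_subject")
  expect_error(fd_generate_cohort(1, 2, seed = 1), "at least 2 subjects")
  coh2 <- fd_generate_cohort(4, 10, seed = 5, duration = 8)
  expect_identical(coh, coh2)
  ## a 2 x 2 cohort is the minimal LOSO input
  expect_silent(mini <- fd_generate_cohort(2, 2, seed = 9, duration = 8))
  expect_length(mini$subjects, 2)
})

test_that("fall trials out-accelerate ADL trials on average", {
  coh <- tiny_cohort(seed = 11, n_subjects = 3, trials = 6)
  trials <- unlist(coh$trials, recursive = FALSE)
  peak <- function(tr) max(sqrt(rowSums(as.matrix(tr$imu[, 2:4])^2)))
  is_fall <- vapply(trials, fallfuse:::fd_is_fall_trial, TRUE)
  expect_gt(mean(vapply(trials[is_fall], peak, 1)),
            mean(vapply(trials[!is_fall], peak, 1)))
})

test_that("falls produce a sustained prone posture; walking never does", {
  nz <- quiet_noise()
  fall <- fd_generate_trial(fd_script("fall_forward", duration = 10),
                            noise = nz, seed = 13)
  flags <- fd_posture_flags(fall$pose)
  streak <- fd_prone_streak(flags, required = 30)
  expect_true(streak$confirmed)
  ## the streak begins after the event onset
  first_prone <- min(which(streak$confirmed_frames))
  expect_gte(fall$pose$t[first_prone], fall$script$event_interval[1])
  walk <- fd_generate_trial(fd_script("walk", duration = 10),
                            noise = nz, seed = 14)
  expect_false(any(fd_posture_flags(walk$pose) == "prone"))
})

test_that("sensor clipping and landmark ranges are enforced by construction", {
  tr <- fd_generate_trial(fd_script("fall_backward", duration = 10),
                          noise = fd_noise_config(impulse_peak_range = c(20, 20)),
                          seed = 15)
  expect_true(all(abs(as.matrix(tr$imu[, 2:4])) <= 16))
  expect_true(all(abs(as.matrix(tr$imu[, 5:7])) <= 2000))
  expect_true(all(tr$pose$lm >= 0 & tr$pose$lm <= 1))
})
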