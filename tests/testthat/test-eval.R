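## Pipeline-level protocol tests run on a deliberately tiny simulated cohort
## (2 subjects x 4 ten-second trials, reduced network sizes).

loso_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- tiny_cohort(seed = 91)
      cache <<- fd_loso_run(coh, config = tiny_config(), seed = 91)
    }
    cache
  }
})

test_that("LOSO holds out each subject exactly once, trained on the rest", {
  loso <- loso_fixture()
  expect_length(loso$folds, 2)
  held <- vapply(loso$folds, function(f) f$subject, "")
  expect_setequal(held, c("S01", "S02"))
  for (f in loso$folds) {
    expect_false(f$subject %in% f$train_subjects)
    expect_setequal(c(f$subject, f$train_subjects), held)
  }
  ## every evaluated epoch belongs to the fold's held-out subject
  for (s in held) {
    ep <- loso$epochs[loso$epochs$subject == s, ]
    expect_gt(nrow(ep), 0)
  }
})

test_that("micro-averaged rates equal rates of pooled counts", {
  loso <- loso_fixture()
  for (sys in c("fused", "imu", "vision")) {
    pooled <- Reduce(function(acc, f) acc + unlist(f[[sys]][c("tp", "fp",
                                                              "tn", "fn")]),
                     loso$folds, c(tp = 0, fp = 0, tn = 0, fn = 0))
    expect_equal(loso$micro[[sys]]$fpr,
                 unname(pooled["fp"] / (pooled["fp"] + pooled["tn"])))
    expect_equal(loso$micro[[sys]]$tp, unname(pooled["tp"]))
  }
  ## epochs table is consistent with the pooled totals
  tot <- Reduce(`+`, lapply(loso$folds, function(f) {
    sum(unlist(f$fused[c("tp", "fp", "tn", "fn")]))
  }))
  expect_equal(nrow(loso$epochs), tot)
})

test_that("decision tables are reproducible for a fixed trial and detector", {
  loso <- loso_fixture()
  coh <- tiny_cohort(seed = 91)
  cfg <- tiny_config()
  det <- fall_detector(coh, subjects = "S01", config = cfg, seed = 3)
  tr <- coh$trials[["S02"]][[1]]
  d1 <- predict(det, tr)
  d2 <- predict(det, tr)
  expect_identical(d1, d2)
  ## fall trials yield at least one epoch overlapping the scripted event
  ## with an elevated anomaly score
  fall_tr <- Filter(fallfuse:::fd_is_fall_trial, coh$trials[["S02"]])[[1]]
  dec <- predict(det, fall_tr)
  expect_true(any(dec$truth))
  expect_gt(max(dec$s_anomaly[dec$truth], na.rm = TRUE),
            median(dec$s_anomaly[!dec$truth], na.rm = TRUE))
})

test_that("calibration sampling is stratified, sized K and disjoint from test", {
  set.seed(92)
  for (rep in 1:20) {
    n <- sample(12:40, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    K <- sample(1:10, 1)
    cal <- fallfuse:::.fd_sample_cal(labels, K, seed = rep)
    expect_length(cal, min(K, n - 1))
    expect_equal(anyDuplicated(cal), 0)
    test_idx <- setdiff(seq_len(n), cal)
    expect_length(intersect(cal, test_idx), 0)
    expect_gt(length(test_idx), 0)
    if (K >= 2) {
      ## both classes represented when K allows it
      expect_length(unique(labels[cal]), 2)
    }
  }
})

test_that("few-shot personalization improves on the untuned head", {
  sets <- fd_simulate_score_cohort(6, n_fall = 12, n_normal = 24, seed = 93)
  fs <- fd_few_shot_curve(sets, K_range = c(2, 6, 10), n_seeds = 3,
                          seed = 93)
  expect_equal(fs$summary$K, c(2, 6, 10))
  expect_true(all(fs$summary$mean_f1 >= 0 & fs$summary$mean_f1 <= 1))
  expect_true(all(fs$summary$ci_upper >= fs$summary$mean_f1))
  ## tuned heads beat the untuned baseline on shifted subjects
  expect_gt(fs$summary$mean_f1[fs$summary$K == 10], mean(fs$baseline_f1))
  ## oversized K is capped with a warning (one per affected subject)
  tiny <- list(A = sets[[1]][1:5, ], B = sets[[2]][1:5, ])
  warns <- testthat::capture_warnings(
    fd_few_shot_curve(tiny, K_range = 5, n_seeds = 1, seed = 1))
  expect_true(any(grepl("capped", warns)))
})

test_that("the saturating-exponential fit recovers known parameters", {
  m <- seq(2, 16, by = 2)
  f1 <- 0.97 - 0.10 * exp(-0.4 * m)
  fit <- fd_fit_learning_curve(m, f1)
  expect_lt(abs(fit$a - 0.97), 1e-4)
  expect_lt(abs(fit$b - 0.10), 1e-4)
  expect_lt(abs(fit$c - 0.4), 1e-4)
  expect_equal(fit$fitted, f1, tolerance = 1e-6)
  expect_equal(fit$asymptote, fit$a)

  flat <- fd_fit_learning_curve(m, rep(0.9, length(m)))
  expect_lt(abs(flat$b), 1e-6)
  expect_true(flat$saturated)
})

test_that("the asymptote's bootstrap interval covers a noisy truth", {
  set.seed(94)
  m <- seq(2, 16, by = 2)
  truth <- 0.95 - 0.12 * exp(-0.35 * m)
  reps <- matrix(rep(truth, each = 10) + rnorm(80, 0, 0.005), 10, 8)
  fit <- fd_fit_learning_curve(m, colMeans(reps), replicates = reps,
                               n_boot = 200, seed = 94)
  expect_false(is.null(fit$asymptote_ci))
  expect_lt(fit$asymptote_ci[1], 0.96)
  expect_gt(fit$asymptote_ci[2], 0.94)
})

test_that("the learning-curve driver runs LOSO within sampled subsets", {
  coh <- tiny_cohort(seed = 95, n_subjects = 3, trials = 2, duration = 10)
  lc <- fd_learning_curve(coh, m_grid = c(2, 3), repeats = 2,
                          config = tiny_config(), seed = 95)
  expect_equal(lc$points$m, c(2, 3))
  expect_equal(dim(lc$replicates), c(2, 2))
  expect_true(all(lc$replicates >= 0 & lc$replicates <= 1, na.rm = TRUE))
  expect_error(fd_learning_curve(coh, m_grid = c(2, 8), repeats = 1),
               "exceeds cohort size")
})
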