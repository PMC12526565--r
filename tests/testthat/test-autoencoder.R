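test_that("reconstruction error equals the double-loop oracle", {
  ## unit residual on every channel and timestep: squared 6-dim norm = 6
  x <- matrix(0, 60, 6)
  expect_equal(fd_reconstruction_mse(x, x), 0)
  expect_equal(fd_reconstruction_mse(x, x + 1), 6)

  set.seed(31)
  for (rep in 1:5) {
    a <- matrix(rnorm(360), 60, 6)
    b <- matrix(rnorm(360), 60, 6)
    oracle <- 0
    for (t in 1:60) for (cc in 1:6) oracle <- oracle + (a[t, cc] - b[t, cc])^2
    oracle <- oracle / 60
    expect_equal(fd_reconstruction_mse(a, b), oracle, tolerance = 1e-12)
  }
  expect_error(fd_reconstruction_mse(x, matrix(0, 30, 6)), "shape mismatch")
})

test_that("threshold calibration follows the linear-interpolation convention", {
  expect_equal(fd_calibrate_tau(1:100)$tau, 95.05)
  expect_equal(fd_calibrate_tau(rep(3.5, 30))$tau, 3.5)
  expect_equal(fd_calibrate_tau(1:100, percentile = 100)$tau, 100)
  expect_warning(tau <- fd_calibrate_tau(1:10), "degraded")
  expect_true(tau$degraded)
  expect_error(fd_calibrate_tau(numeric(0)), "empty")
  ## monotone in the percentile
  set.seed(32)
  errs <- rexp(200)
  taus <- vapply(c(50, 75, 90, 95, 99, 100),
                 function(p) fd_calibrate_tau(errs, p)$tau, 1)
  expect_true(all(diff(taus) >= 0))
})

test_that("anomaly score clamps at 1 and is scale invariant", {
  expect_equal(fd_anomaly_score(0, 2)$score, 0)
  expect_equal(fd_anomaly_score(1, 2)$score, 0.5)
  expect_equal(fd_anomaly_score(4, 2)$score, 1)
  expect_false(fd_anomaly_score(2, 2)$abnormal)  # strict inequality
  expect_true(fd_anomaly_score(2 + 1e-9, 2)$abnormal)
  expect_error(fd_anomaly_score(-1, 2), "negative")
  set.seed(33)
  mse <- sort(rexp(50)); tau <- 1.3
  s1 <- fd_anomaly_score(mse, tau)$score
  expect_true(all(diff(s1) >= 0))                     # non-decreasing
  s2 <- fd_anomaly_score(mse * 7, tau * 7)$score      # common rescaling
  expect_equal(s1, s2)
})

test_that("autoencoder construction is shaped and seeded as specified", {
  m <- fd_autoencoder(hidden = 8, seed = 4)
  expect_equal(m$latent, 16)
  X <- array(0, c(2, 60, 6))
  out <- fallfuse:::ae_forward(m$params, X, m$hidden)
  expect_equal(dim(out$Xhat), c(2, 60, 6))
  expect_true(all(is.finite(out$Xhat)))
  m2 <- fd_autoencoder(hidden = 8, seed = 4)
  expect_identical(m$params, m2$params)
  expect_error(fd_autoencoder(input_dim = 5), "fixed at 6")
  expect_error(fd_autoencoder(hidden = 8, latent = 99), "2 \\* hidden")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(34)
  m <- fd_autoencoder(hidden = 4, seed = 3)
  X <- array(rnorm(2 * 5 * 6), c(2, 5, 6))
  fwd <- fallfuse:::ae_forward(m$params, X, 4)
  g <- fallfuse:::ae_backward(m$params, X, fwd, 4)
  v <- fallfuse:::fd_flatten(m$params)
  gv <- fallfuse:::fd_flatten(g[names(m$params)])
  idx <- sample(length(v), 25)
  for (i in idx) {
    e <- 1e-5
    vp <- v; vp[i] <- v[i] + e
    l1 <- fallfuse:::ae_loss(X, fallfuse:::ae_forward(
      fallfuse:::fd_unflatten(vp, m$params), X, 4)$Xhat)$loss
    vp[i] <- v[i] - e
    l2 <- fallfuse:::ae_loss(X, fallfuse:::ae_forward(
      fallfuse:::fd_unflatten(vp, m$params), X, 4)$Xhat)$loss
    num <- (l1 - l2) / (2 * e)
    expect_lt(abs(num - gv[i]) / (abs(num) + abs(gv[i]) + 1e-8), 1e-3)
  }
})

test_that("the autoencoder can memorize a single repeated window", {
  set.seed(35)
  w <- matrix(sin(seq(0, 6 * pi, length.out = 60)) %o% runif(6, -1, 1), 60, 6)
  ws <- lapply(1:50, function(i) list(samples = w))
  ae <- fd_autoencoder(hidden = 8, seed = 2)
  e0 <- fd_reconstruction_errors(ae, ws)[1]
  ae <- fd_train_autoencoder(ae, ws, lr = 5e-3, epochs = 120, patience = 120,
                             seed = 3)
  e1 <- fd_reconstruction_errors(ae, ws)[1]
  expect_lt(e1 / e0, 0.01)
})

test_that("training is deterministic and early stopping respects the budget", {
  set.seed(36)
  X <- array(rnorm(30 * 20 * 6, sd = 0.5), c(30, 20, 6))
  run <- function() {
    ae <- fd_autoencoder(hidden = 4, seed = 9)
    fd_train_autoencoder(ae, X, lr = 2e-3, epochs = 6, patience = 2, seed = 5)
  }
  a <- run(); b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_lte(nrow(a$history), 6)
  expect_lte(a$stopped_epoch, 6)
  expect_error(fd_train_autoencoder(fd_autoencoder(hidden = 4),
                                    array(0, c(1, 20, 6))),
               "at least 2")
})

test_that("scores separate fall windows from routine windows after training", {
  coh <- tiny_cohort(seed = 41, n_subjects = 2, trials = 4)
  trials <- unlist(coh$trials, recursive = FALSE)
  zs <- fd_train_stats(lapply(trials, function(tr) tr$imu[, -1]))
  nonfall <- list(); fallw <- list()
  for (tr in trials) {
    pp <- fd_preprocess(tr$imu[, -1], stats = zs)
    for (w in fd_make_windows(pp, t = tr$imu$t)) {
      ev <- tr$script$event_interval
      if (!is.null(ev) && w$interval[1] < ev[2] && w$interval[2] > ev[1]) {
        fallw[[length(fallw) + 1]] <- w
      } else {
        nonfall[[length(nonfall) + 1]] <- w
      }
    }
  }
  ae <- fd_autoencoder(hidden = 8, seed = 2)
  ae <- fd_train_autoencoder(ae, nonfall, lr = 1e-3, epochs = 5,
                             patience = 3, seed = 4)
  tau <- fd_calibrate_tau(ae$train_errors)
  s_nf <- fd_anomaly_score(fd_reconstruction_errors(ae, nonfall), tau)$score
  s_f <- fd_anomaly_score(fd_reconstruction_errors(ae, fallw), tau)$score
  expect_gt(mean(s_f), mean(s_nf))
  expect_gt(median(s_f), median(s_nf))
})
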