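test_that("the conjunctive rule labels the canonical score pairs", {
  expect_equal(fd_fuse(0.8, 0.9), "FALL")
  expect_equal(fd_fuse(0.8, 0.3), "LOW_CONFIDENCE")
  expect_equal(fd_fuse(0.3, 0.8), "LOW_CONFIDENCE")
  expect_equal(fd_fuse(0.3, 0.2), "NORMAL")
  ## boundary: scores equal to alpha do NOT exceed it
  expect_equal(fd_fuse(0.70, 0.9), "LOW_CONFIDENCE")
  expect_equal(fd_fuse(0.70, 0.70), "NORMAL")
  expect_error(fd_fuse(1.2, 0.5), "outside")
})

test_that("the rule matches a brute-force truth table on the score grid", {
  g <- seq(0, 1, by = 0.01)
  grid <- expand.grid(p = g, s = g)
  got <- fd_fuse(grid$p, grid$s)
  oracle <- apply(grid, 1, function(r) {
    v <- r["p"] > 0.70; s <- r["s"] > 0.70
    if (v && s) "FALL" else if (v || s) "LOW_CONFIDENCE" else "NORMAL"
  })
  expect_identical(got, unname(oracle))
})

test_that("raising either score never demotes the label", {
  ord <- c(NORMAL = 1, LOW_CONFIDENCE = 2, FALL = 3)
  g <- seq(0, 1, by = 0.05)
  for (p in g) {
    labs <- ord[fd_fuse(rep(p, length(g)), g)]
    expect_true(all(diff(labs) >= 0))
    labs <- ord[fd_fuse(g, rep(p, length(g)))]
    expect_true(all(diff(labs) >= 0))
  }
})

test_that("a missing IMU score can never produce FALL", {
  expect_equal(fd_fuse(0.99, NA), "LOW_CONFIDENCE")
  expect_equal(fd_fuse(0.2, NA), "NORMAL")
})

test_that("epoch alignment pairs by window-centre proximity", {
  vis <- seq(0.5, 9.5, by = 1)            # ten 1-s segments
  imu_c <- seq(0.6, 9.6, by = 0.6)        # window centres every 0.6 s
  sc <- seq_along(imu_c) / length(imu_c)
  paired <- fd_align_epochs(vis, imu_c, sc)
  expect_length(paired, 10)
  expect_false(anyNA(paired))
  ## the paired score is the max among windows within +/- 0.6 s
  expect_equal(paired[1], max(sc[abs(imu_c - 0.5) <= 0.6]))
  ## a 100 ms stream offset changes nothing
  expect_equal(fd_align_epochs(vis, imu_c + 0.1, sc), paired)
  ## a 3-s gap leaves 3 epochs unpaired
  keep <- imu_c < 3 | imu_c > 6
  gapped <- fd_align_epochs(vis, imu_c[keep], sc[keep])
  expect_equal(sum(is.na(gapped)), 3)
})

test_that("the fresh fusion head reproduces the AND rule off the boundary", {
  head <- fd_fusion_head()
  expect_lt(head$n_params, 5000)
  expect_gt(fd_fusion_head_predict(head, 0.9, 0.9), 0.5)
  expect_lt(fd_fusion_head_predict(head, 0.1, 0.1), 0.5)
  expect_lt(fd_fusion_head_predict(head, 0.9, 0.1), 0.5)
  g <- seq(0, 1, by = 0.01)
  grid <- expand.grid(p = g, s = g)
  off_band <- abs(grid$p - 0.70) >= 0.05 & abs(grid$s - 0.70) >= 0.05
  ph <- fd_fusion_head_predict(head, grid$p, grid$s)
  rule_fall <- fd_fuse(grid$p, grid$s) == "FALL"
  agree <- (ph > 0.5) == rule_fall
  expect_gte(mean(agree[off_band]), 0.99)
})

test_that("fine-tuning adapts the head to a shifted subject", {
  ## this subject's falls score (0.6, 0.9): below alpha on vision, so the
  ## untuned AND rule misses them
  set.seed(71)
  p <- c(rnorm(15, 0.60, 0.03), rnorm(25, 0.2, 0.05))
  s <- c(rnorm(15, 0.90, 0.03), rnorm(25, 0.3, 0.05))
  y <- rep(c(1, 0), c(15, 25))
  head <- fd_fusion_head()
  expect_lt(fd_fusion_head_predict(head, 0.6, 0.9), 0.5)
  tuned <- fd_fine_tune_head(head, p, s, y)
  expect_gt(fd_fusion_head_predict(tuned, 0.6, 0.9), 0.5)
  ## normals are still rejected
  expect_lt(fd_fusion_head_predict(tuned, 0.2, 0.3), 0.5)
  ## loss did not increase over the run
  expect_lte(tail(tuned$loss_trace, 1), tuned$loss_trace[1])
  ## exactly 50 iterations by default, parameter count unchanged
  expect_length(tuned$loss_trace, 50)
  expect_equal(length(fallfuse:::fd_flatten(tuned$params)), head$n_params)
  expect_error(fd_fine_tune_head(head, numeric(0), numeric(0), numeric(0)),
               "empty")
})
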