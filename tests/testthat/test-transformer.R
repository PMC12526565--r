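test_that("transformer outputs proper probabilities and seeds reproducibly", {
  tf <- fd_transformer(d_model = 16, n_layers = 1, n_heads = 2, seed = 8)
  feat <- matrix(runif(30 * 66), 30, 66)
  p <- fd_transformer_probs(tf, feat)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  tf2 <- fd_transformer(d_model = 16, n_layers = 1, n_heads = 2, seed = 8)
  expect_identical(tf$params, tf2$params)
  expect_error(fd_transformer(input_dim = 60), "fixed at 66")
  expect_error(fd_transformer(d_model = 30, n_heads = 8), "divisible")
})

test_that("transformer gradients match finite differences", {
  set.seed(61)
  tf <- fd_transformer(d_model = 8, n_layers = 2, n_heads = 2, seq_len = 5,
                       seed = 4)
  feat <- matrix(runif(5 * 66), 5, 66)
  fwd <- fallfuse:::tf_forward(tf, feat, keep_cache = TRUE)
  g <- fallfuse:::tf_backward(tf, fwd, 1L)
  v <- fallfuse:::fd_flatten(tf$params)
  gv <- fallfuse:::fd_flatten(g)
  lossfn <- function(vv) {
    t2 <- tf; t2$params <- fallfuse:::fd_unflatten(vv, tf$params)
    -log(fallfuse:::tf_forward(t2, feat)$probs[1])
  }
  idx <- sample(length(v), 30)
  for (i in idx) {
    e <- 1e-5
    vp <- v; vp[i] <- v[i] + e; l1 <- lossfn(vp)
    vp[i] <- v[i] - e; l2 <- lossfn(vp)
    num <- (l1 - l2) / (2 * e)
    expect_lt(abs(num - gv[i]) / (abs(num) + abs(gv[i]) + 1e-8), 1e-3)
  }
})

test_that("stratified split yields the 70/15/15 proportions", {
  labels <- rep(c("fallen", "normal"), each = 50)
  sp <- fd_stratified_split(labels, seed = 5)
  expect_length(sp$train, 70)
  expect_length(sp$val, 16)   # rounded per class: 8 + 8
  expect_length(sp$test, 14)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
  ## both classes present in every part
  for (part in sp) expect_length(unique(labels[part]), 2)
})

test_that("the transformer separates strongly separated synthetic segments", {
  fx <- fake_segments(10, seed = 6)
  tf <- fd_transformer(d_model = 16, n_layers = 1, n_heads = 2, seed = 2)
  tf <- fd_train_transformer(tf, fx$segments, fx$labels, lr = 5e-3,
                             batch_size = 10, epochs = 15, patience = 15,
                             split = c(0.8, 0.2, 0), seed = 3)
  pr <- fd_transformer_probs(tf, fx$segments)[, "fallen"]
  acc <- mean((pr > 0.5) == (fx$labels == "fallen"))
  expect_equal(acc, 1)
  ## training loss at the accepted checkpoint is below the initial loss
  expect_lt(min(tf$history$val), tf$history$val[1] + 1e-9)
})

test_that("single-class training data is rejected", {
  fx <- fake_segments(6, seed = 7)
  keep <- fx$labels == "normal"
  tf <- fd_transformer(d_model = 16, n_layers = 1, n_heads = 2, seed = 2)
  expect_error(
    fd_train_transformer(tf, fx$segments[keep], fx$labels[keep], seed = 1),
    "both classes")
})

test_that("posture gating scales the transformer probability as configured", {
  fx <- fake_segments(2, seed = 8)
  tf <- fd_transformer(d_model = 16, n_layers = 1, n_heads = 2, seed = 2)
  seg <- fx$segments[[1]]
  raw <- fd_vision_probability(tf, seg, prone_in_span = FALSE, mode = "raw")
  gated_on <- fd_vision_probability(tf, seg, prone_in_span = TRUE)
  gated_off <- fd_vision_probability(tf, seg, prone_in_span = FALSE)
  hard_off <- fd_vision_probability(tf, seg, prone_in_span = FALSE,
                                    mode = "hard_and")
  expect_equal(gated_on$p_fall, raw$p_fall)
  expect_equal(gated_off$p_fall, raw$p_fall * 0.5)
  expect_equal(hard_off$p_fall, 0)
  expect_equal(raw$p_transformer, raw$p_fall)
  ## incomplete segments are rejected
  short <- list(features = seg$features[1:10, ])
  expect_error(fd_vision_probability(tf, short, TRUE), "incomplete")
})
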