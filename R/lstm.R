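## Minimal batched LSTM layer: forward pass with caches and exact
## backpropagation-through-time, in base R matrix algebra. Gate order in the
## fused weight matrices is [input | forget | cell | output]; the forget-gate
## bias is initialised to +1 (standard remedy for early vanishing memory).

lstm_init <- function(input_dim, hidden) {
  p <- list(
    W = glorot(input_dim, 4 * hidden),
    U = glorot(hidden, 4 * hidden),
    b = rep(0, 4 * hidden)
  )
  p$b[(hidden + 1):(2 * hidden)] <- 1
  attr(p, "hidden") <- hidden
  p
}

## X: (B, T, D) array. Returns H_seq (B, T, H) plus caches for backprop.
lstm_forward <- function(params, X) {
  B <- dim(X)[1]; Tt <- dim(X)[2]
  H <- ncol(params$U) / 4
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  oo <- (3 * H + 1):(4 * H)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  H_seq <- array(0, c(B, Tt, H))
  cache <- list(i = array(0, c(B, Tt, H)), f = array(0, c(B, Tt, H)),
                g = array(0, c(B, Tt, H)), o = array(0, c(B, Tt, H)),
                c = array(0, c(B, Tt, H)), tc = array(0, c(B, Tt, H)),
                hp = array(0, c(B, Tt, H)), cp = array(0, c(B, Tt, H)))
  for (t in seq_len(Tt)) {
    x_t <- matrix(X[, t, ], nrow = B)
    z <- x_t %*% params$W + h %*% params$U +
      matrix(params$b, B, 4 * H, byrow = TRUE)
    gi <- sigmoid(z[, ii, drop = FALSE])
    gf <- sigmoid(z[, ff, drop = FALSE])
    gc_ <- tanh(z[, gg, drop = FALSE])
    go <- sigmoid(z[, oo, drop = FALSE])
    cache$hp[, t, ] <- h; cache$cp[, t, ] <- cc
    cc <- gf * cc + gi * gc_
    tc <- tanh(cc)
    h <- go * tc
    cache$i[, t, ] <- gi; cache$f[, t, ] <- gf; cache$g[, t, ] <- gc_
    cache$o[, t, ] <- go; cache$c[, t, ] <- cc; cache$tc[, t, ] <- tc
    H_seq[, t, ] <- h
  }
  list(H_seq = H_seq, cache = cache, X = X)
}

## dH_seq: (B, T, H) gradients w.r.t. every emitted h_t.
## Returns dX (B, T, D) and parameter gradients.
lstm_backward <- function(params, fwd, dH_seq) {
  X <- fwd$X; cache <- fwd$cache
  B <- dim(X)[1]; Tt <- dim(X)[2]; D <- dim(X)[3]
  H <- ncol(params$U) / 4
  dW <- params$W * 0; dU <- params$U * 0; db <- params$b * 0
  dX <- array(0, c(B, Tt, D))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    gi <- matrix(cache$i[, t, ], B); gf <- matrix(cache$f[, t, ], B)
    gc_ <- matrix(cache$g[, t, ], B); go <- matrix(cache$o[, t, ], B)
    tc <- matrix(cache$tc[, t, ], B); cp <- matrix(cache$cp[, t, ], B)
    hp <- matrix(cache$hp[, t, ], B)
    dh <- matrix(dH_seq[, t, ], B) + dh_next
    do_pre <- dh * tc * go * (1 - go)
    dc <- dc_next + dh * go * (1 - tc * tc)
    di_pre <- dc * gc_ * gi * (1 - gi)
    df_pre <- dc * cp * gf * (1 - gf)
    dg_pre <- dc * gi * (1 - gc_ * gc_)
    dc_next <- dc * gf
    dZ <- cbind(di_pre, df_pre, dg_pre, do_pre)
    x_t <- matrix(X[, t, ], nrow = B)
    dW <- dW + crossprod(x_t, dZ)
    dU <- dU + crossprod(hp, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(params$W)
    dh_next <- dZ %*% t(params$U)
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}
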