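## Transformer encoder for 1-s pose-landmark sequences (30 frames x 66
## features), implemented natively: learned input projection, sinusoidal
## positional encoding, pre-norm encoder blocks (multi-head self-attention +
## position-wise feed-forward), mean pooling and a 2-logit softmax head.
## Forward, exact backpropagation and Adam live here.

fd_positional_encoding <- function(Tt, d) {
  pe <- matrix(0, Tt, d)
  pos <- 0:(Tt - 1)
  for (i in seq(0, d - 1, by = 2)) {
    div <- 10000^(i / d)
    pe[, i + 1] <- sin(pos / div)
    if (i + 2 <= d) pe[, i + 2] <- cos(pos / div)
  }
  pe
}

#' Build a pose-sequence Transformer classifier
#'
#' Defaults follow the reference architecture: input feature size 66
#' (33 landmarks x 2 coordinates), model dimension 256, 4 encoder layers
#' with 8-head self-attention, sequence length 30, feed-forward width 4x the
#' model dimension, and a softmax head over \{fallen, normal\}.
#'
#' @param input_dim Per-frame feature size; fixed at 66.
#' @param d_model Model (embedding) dimension.
#' @param n_layers Number of encoder layers.
#' @param n_heads Attention heads (must divide `d_model`).
#' @param seq_len Frames per segment.
#' @param ff_mult Feed-forward width multiplier.
#' @param seed Integer seed for initialization.
#' @return Object of class `fd_transformer`.
#' @export
fd_transformer <- function(input_dim = 66, d_model = 256, n_layers = 4,
                           n_heads = 8, seq_len = 30, ff_mult = 4, seed = 1) {
  .fd_assert(input_dim == 66,
             "input_dim is fixed at 66 (33 landmarks x 2), got %d", input_dim)
  .fd_assert(d_model %% n_heads == 0,
             "d_model (%d) must be divisible by n_heads (%d)",
             d_model, n_heads)
  set.seed(fd_subseed(seed, 51L))
  d <- d_model; ff <- ff_mult * d
  params <- list(W_in = glorot(input_dim, d), b_in = rep(0, d))
  for (l in seq_len(n_layers)) {
    p <- paste0("l", l, "_")
    params[[paste0(p, "ln1_g")]] <- rep(1, d)
    params[[paste0(p, "ln1_b")]] <- rep(0, d)
    params[[paste0(p, "Wq")]] <- glorot(d, d)
    params[[paste0(p, "Wk")]] <- glorot(d, d)
    params[[paste0(p, "Wv")]] <- glorot(d, d)
    params[[paste0(p, "Wo")]] <- glorot(d, d)
    params[[paste0(p, "ln2_g")]] <- rep(1, d)
    params[[paste0(p, "ln2_b")]] <- rep(0, d)
    params[[paste0(p, "W1")]] <- glorot(d, ff)
    params[[paste0(p, "b1")]] <- rep(0, ff)
    params[[paste0(p, "W2")]] <- glorot(ff, d)
    params[[paste0(p, "b2")]] <- rep(0, d)
  }
  params$lnf_g <- rep(1, d)
  params$lnf_b <- rep(0, d)
  params$W_cls <- glorot(d, 2)
  params$b_cls <- rep(0, 2)
  structure(list(params = params, d_model = d, n_layers = n_layers,
                 n_heads = n_heads, seq_len = seq_len, ff_mult = ff_mult,
                 input_dim = input_dim,
                 pe = fd_positional_encoding(seq_len, d),
                 trained = FALSE, seed = seed),
            class = "fd_transformer")
}

#' @export
print.fd_transformer <- function(x, ...) {
  cat("Pose Transformer: 66 ->", x$d_model, "|", x$n_layers, "layers x",
      x$n_heads, "heads | seq", x$seq_len, "|",
      length(fd_flatten(x$params)), "parameters |",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

.ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(x), ncol(x), byrow = TRUE),
       xhat = xhat, inv = inv, xc = xc)
}

.ln_backward <- function(dy, cache, g) {
  d <- ncol(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  ## per-row layernorm backward
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - rs1 / d - cache$xhat * rs2 / d)
  list(dx = dx, dg = dg, db = db)
}

## Forward pass on one segment (seq_len x 66). Returns class probabilities
## and, when wanted, the caches needed for the backward pass.
tf_forward <- function(model, feat, keep_cache = FALSE) {
  p <- model$params
  nh <- model$n_heads; d <- model$d_model; dh <- d / nh
  Tt <- model$seq_len
  H <- feat %*% p$W_in + matrix(p$b_in, Tt, d, byrow = TRUE) + model$pe
  caches <- vector("list", model$n_layers)
  for (l in seq_len(model$n_layers)) {
    pr <- paste0("l", l, "_")
    ln1 <- .ln_forward(H, p[[paste0(pr, "ln1_g")]], p[[paste0(pr, "ln1_b")]])
    A <- ln1$y
    Q <- A %*% p[[paste0(pr, "Wq")]]
    K <- A %*% p[[paste0(pr, "Wk")]]
    V <- A %*% p[[paste0(pr, "Wv")]]
    O <- matrix(0, Tt, d)
    Ph <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
      P <- softmax_rows(S)
      O[, cols] <- P %*% V[, cols, drop = FALSE]
      Ph[[h]] <- P
    }
    attn <- O %*% p[[paste0(pr, "Wo")]]
    H2 <- H + attn
    ln2 <- .ln_forward(H2, p[[paste0(pr, "ln2_g")]], p[[paste0(pr, "ln2_b")]])
    Z1 <- ln2$y %*% p[[paste0(pr, "W1")]] +
      matrix(p[[paste0(pr, "b1")]], Tt, model$ff_mult * d, byrow = TRUE)
    R <- pmax(Z1, 0)
    FF <- R %*% p[[paste0(pr, "W2")]] +
      matrix(p[[paste0(pr, "b2")]], Tt, d, byrow = TRUE)
    Hout <- H2 + FF
    if (keep_cache) {
      caches[[l]] <- list(H = H, ln1 = ln1, A = A, Q = Q, K = K, V = V,
                          O = O, Ph = Ph, H2 = H2, ln2 = ln2, Z1 = Z1, R = R)
    }
    H <- Hout
  }
  lnf <- .ln_forward(H, p$lnf_g, p$lnf_b)
  pooled <- colMeans(lnf$y)
  logits <- as.numeric(pooled %*% p$W_cls + p$b_cls)
  pr_ <- exp(logits - max(logits)); pr_ <- pr_ / sum(pr_)
  out <- list(probs = pr_, pooled = pooled, logits = logits)
  if (keep_cache) {
    out$caches <- caches; out$lnf <- lnf; out$Hfinal <- H; out$feat <- feat
  }
  out
}

## Backward pass for cross-entropy loss on one segment; y is 1 (fallen) or
## 2 (normal), matching the probability ordering. Returns gradient list.
tf_backward <- function(model, fwd, y) {
  p <- model$params
  nh <- model$n_heads; d <- model$d_model; dh <- d / nh
  Tt <- model$seq_len
  g <- lapply(p, function(z) z * 0)
  dlogits <- fwd$probs
  dlogits[y] <- dlogits[y] - 1
  g$W_cls <- outer(fwd$pooled, dlogits)
  g$b_cls <- dlogits
  dpooled <- as.numeric(p$W_cls %*% dlogits)
  dZf <- matrix(dpooled, Tt, d, byrow = TRUE) / Tt
  lb <- .ln_backward(dZf, fwd$lnf, p$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dH <- lb$dx
  for (l in rev(seq_len(model$n_layers))) {
    pr <- paste0("l", l, "_")
    cc <- fwd$caches[[l]]
    ## feed-forward sub-block
    dFF <- dH                      # residual: dHout flows to both H2 and FF
    dR <- dFF %*% t(p[[paste0(pr, "W2")]])
    g[[paste0(pr, "W2")]] <- crossprod(cc$R, dFF)
    g[[paste0(pr, "b2")]] <- colSums(dFF)
    dZ1 <- dR * (cc$Z1 > 0)
    g[[paste0(pr, "W1")]] <- crossprod(cc$ln2$y, dZ1)
    g[[paste0(pr, "b1")]] <- colSums(dZ1)
    dln2y <- dZ1 %*% t(p[[paste0(pr, "W1")]])
    lb2 <- .ln_backward(dln2y, cc$ln2, p[[paste0(pr, "ln2_g")]])
    g[[paste0(pr, "ln2_g")]] <- lb2$dg
    g[[paste0(pr, "ln2_b")]] <- lb2$db
    dH2 <- dH + lb2$dx
    ## attention sub-block
    dattn <- dH2
    g[[paste0(pr, "Wo")]] <- crossprod(cc$O, dattn)
    dO <- dattn %*% t(p[[paste0(pr, "Wo")]])
    dQ <- matrix(0, Tt, d); dK <- matrix(0, Tt, d); dV <- matrix(0, Tt, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      P <- cc$Ph[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dP <- dOh %*% t(Vh)
      dV[, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) / sqrt(dh)
      dK[, cols] <- (crossprod(dS, cc$Q[, cols, drop = FALSE])) / sqrt(dh)
    }
    g[[paste0(pr, "Wq")]] <- crossprod(cc$A, dQ)
    g[[paste0(pr, "Wk")]] <- crossprod(cc$A, dK)
    g[[paste0(pr, "Wv")]] <- crossprod(cc$A, dV)
    dA <- dQ %*% t(p[[paste0(pr, "Wq")]]) + dK %*% t(p[[paste0(pr, "Wk")]]) +
      dV %*% t(p[[paste0(pr, "Wv")]])
    lb1 <- .ln_backward(dA, cc$ln1, p[[paste0(pr, "ln1_g")]])
    g[[paste0(pr, "ln1_g")]] <- lb1$dg
    g[[paste0(pr, "ln1_b")]] <- lb1$db
    dH <- dH2 + lb1$dx
  }
  g$W_in <- crossprod(fwd$feat, dH)
  g$b_in <- colSums(dH)
  g[names(p)]
}

#' Class probabilities for pose segments
#'
#' @param model An [fd_transformer()].
#' @param segments List of segments (each with a `features` matrix) or a
#'   single feature matrix.
#' @return Matrix with columns `fallen`, `normal` (rows sum to 1).
#' @export
fd_transformer_probs <- function(model, segments) {
  if (is.matrix(segments)) segments <- list(list(features = segments))
  out <- t(vapply(segments, function(s) {
    f <- if (is.list(s)) s$features else s
    tf_forward(model, f)$probs
  }, numeric(2)))
  colnames(out) <- c("fallen", "normal")
  out
}

#' Stratified train/validation/test split
#'
#' @param labels Class labels.
#' @param proportions Split proportions summing to 1 (train, val, test).
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
fd_stratified_split <- function(labels, proportions = c(0.7, 0.15, 0.15),
                                seed = 1) {
  .fd_assert(abs(sum(proportions) - 1) < 1e-9, "proportions must sum to 1")
  set.seed(fd_subseed(seed, 61L))
  tr <- integer(); va <- integer(); te <- integer()
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- round(proportions[1] * n)
    n_va <- round(proportions[2] * n)
    tr <- c(tr, idx[seq_len(n_tr)])
    va <- c(va, idx[n_tr + seq_len(min(n_va, n - n_tr))])
    te <- c(te, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  list(train = sort(tr), val = sort(va), test = sort(te))
}

#' Train the pose Transformer
#'
#' Cross-entropy training with Adam. The default recipe uses learning rate
#' 1e-4 with cosine annealing, batch size 64, up to 40 epochs and early
#' stopping after 5 epochs without validation improvement; the
#' best-validation checkpoint is returned. An alternative constant-rate
#' recipe (lr 3e-4, no annealing) is selectable via `schedule = "constant"`.
#'
#' @param model An [fd_transformer()].
#' @param segments List of segments (each with `features`).
#' @param labels Character or factor labels, `"fallen"` / `"normal"`.
#' @param lr,batch_size,epochs,patience Training recipe.
#' @param schedule `"cosine"` (default) or `"constant"`.
#' @param split Proportions for the internal stratified
#'   train/validation/test split.
#' @param class_weights `"balanced"` (inverse class frequency, the default —
#'   fallen segments are a small minority of a recording) or `"none"`.
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return Trained model; `$split` holds the index sets, `$history` the loss
#'   trace.
#' @export
fd_train_transformer <- function(model, segments, labels, lr = 1e-4,
                                 batch_size = 64, epochs = 40, patience = 5,
                                 schedule = c("cosine", "constant"),
                                 split = c(0.7, 0.15, 0.15),
                                 class_weights = c("balanced", "none"),
                                 seed = 1, verbose = FALSE) {
  class_weights <- match.arg(class_weights)
  schedule <- match.arg(schedule)
  labels <- as.character(labels)
  .fd_assert(length(segments) == length(labels),
             "segments and labels differ in length")
  .fd_assert(all(labels %in% c("fallen", "normal")),
             "labels must be 'fallen' or 'normal'")
  sp <- fd_stratified_split(labels, split, seed)
  .fd_assert(length(unique(labels[sp$train])) == 2,
             "training split must contain both classes")
  y <- ifelse(labels == "fallen", 1L, 2L)
  wts <- if (class_weights == "balanced") {
    tab <- table(factor(y[sp$train], levels = 1:2))
    w <- as.numeric(sum(tab) / (2 * pmax(tab, 1)))
    w[y]
  } else rep(1, length(y))
  params <- model$params
  st <- adam_init(params)
  best <- list(params = params, val = Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  val_loss <- function(prm) {
    m2 <- model; m2$params <- prm
    ls <- vapply(sp$val, function(i) {
      -wts[i] * log(max(tf_forward(m2, segments[[i]]$features)$probs[y[i]],
                        1e-12))
    }, numeric(1))
    mean(ls)
  }
  stale <- 0L
  for (ep in seq_len(epochs)) {
    lr_ep <- if (schedule == "cosine") {
      lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
    } else lr
    set.seed(fd_subseed(seed, 61L, ep))
    ord <- sample(sp$train)
    ep_loss <- 0; nseen <- 0L
    for (b0 in seq(1, length(ord), by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      gacc <- lapply(params, function(z) z * 0)
      m2 <- model; m2$params <- params
      for (i in bi) {
        fwd <- tf_forward(m2, segments[[i]]$features, keep_cache = TRUE)
        ep_loss <- ep_loss - wts[i] * log(max(fwd$probs[y[i]], 1e-12))
        gi <- tf_backward(m2, fwd, y[i])
        for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] + wts[i] * gi[[nm]]
      }
      gacc <- lapply(gacc, function(z) z / length(bi))
      upd <- adam_step(params, gacc, st, lr = lr_ep)
      params <- upd$params; st <- upd$state
      nseen <- nseen + length(bi)
    }
    vl <- if (length(sp$val) > 0) val_loss(params) else ep_loss / nseen
    hist <- rbind(hist, data.frame(epoch = ep, train = ep_loss / nseen,
                                   val = vl))
    if (verbose) message(sprintf("epoch %d: train %.4f val %.4f lr %.2e",
                                 ep, ep_loss / nseen, vl, lr_ep))
    if (vl < best$val - 1e-9) {
      best <- list(params = params, val = vl, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$split <- sp
  model$stopped_epoch <- best$epoch
  model
}

#' Vision fall probability for one segment (with posture gating)
#'
#' The Transformer's fallen-class probability, optionally gated by the
#' temporal posture vote: in `"gated"` mode (default) the probability is
#' emitted unchanged when a confirmed prone streak overlaps the segment's
#' 1-s span and multiplied by `attenuation` otherwise; `"raw"` disables
#' gating; `"hard_and"` zeroes the probability without prone confirmation.
#'
#' @param model A trained [fd_transformer()].
#' @param segment Segment (with `features`), 30 complete frames.
#' @param prone_in_span Logical: does a confirmed prone streak overlap the
#'   segment's span? (From [fd_prone_streak()]'s `confirmed_frames`.)
#' @param mode `"gated"`, `"raw"` or `"hard_and"`.
#' @param attenuation Multiplier applied without prone confirmation in
#'   `"gated"` mode.
#' @return List with `p_fall`, `prone_confirmed`, `p_transformer`.
#' @export
fd_vision_probability <- function(model, segment, prone_in_span,
                                  mode = c("gated", "raw", "hard_and"),
                                  attenuation = 0.5) {
  mode <- match.arg(mode)
  feat <- if (is.list(segment)) segment$features else segment
  .fd_assert(nrow(feat) == model$seq_len,
             "incomplete segment: %d frames (need %d)",
             nrow(feat), model$seq_len)
  p_tr <- tf_forward(model, feat)$probs[1]
  p <- switch(mode,
              raw = p_tr,
              gated = if (isTRUE(prone_in_span)) p_tr else p_tr * attenuation,
              hard_and = if (isTRUE(prone_in_span)) p_tr else 0)
  list(p_fall = p, prone_confirmed = isTRUE(prone_in_span),
       p_transformer = p_tr)
}
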