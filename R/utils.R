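#' @keywords internal
"_PACKAGE"

## Internal numeric helpers shared by the two network implementations and the
## simulator. All randomness in the package flows through explicit integer
## seeds; sub-seeds are derived arithmetically so that nested stochastic steps
## stay reproducible and independent of evaluation order.

.fd_assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Deterministic sub-seed derivation, kept inside 32-bit integer range.
fd_subseed <- function(seed, ...) {
  ks <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in ks) {
    x <- (x * 69069 + as.double(k) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Row-wise softmax, numerically stabilised.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

## ---- Adam optimiser -------------------------------------------------------
## Parameters live in a named list of matrices/vectors; the Adam state mirrors
## that structure. One step updates in place (functionally).

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Uniform Glorot-style init in [-r, r], r = sqrt(6 / (fan_in + fan_out)).
glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

## Flatten / unflatten a parameter list to one numeric vector (finite-difference
## gradient checks in the test suite rely on these).
fd_flatten <- function(params) unlist(params, use.names = FALSE)

fd_unflatten <- function(vec, template) {
  out <- template
  i <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    piece <- vec[(i + 1L):(i + n)]
    if (is.matrix(template[[nm]])) {
      out[[nm]] <- matrix(piece, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      out[[nm]] <- piece
    }
    i <- i + n
  }
  out
}
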