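# Low-level neural-network operations.
#
# Batches are 4-d arrays (H, W, C, N). Convolutions are 3x3 with "same"
# zero padding, realized as a single BLAS matmul per layer via im2col: the
# padded input is unrolled into an (H*W*N) x (9*C) matrix whose columns are
# ordered (channel, dx, dy) to match the weight-matrix row layout. Pooling
# is 2x2 max with stride 2 (even H, W assumed; enforced by the model
# config). Everything is deterministic given the R RNG state.

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  P <- array(0, c(H + 2, W + 2, C, N))
  P[2:(H + 1), 2:(W + 1), , ] <- x
  X <- matrix(0, H * W * N, 9 * C)
  k <- 0L
  for (ci in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    X[, k] <- as.vector(P[dy + seq_len(H), dx + seq_len(W), ci, , drop = FALSE])
  }
  X
}

conv_forward <- function(x, Wm, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  F_ <- length(b)
  X <- im2col3(x)
  Z <- X %*% Wm
  Z <- Z + matrix(b, nrow(Z), F_, byrow = TRUE)
  out <- aperm(array(Z, c(H, W, N, F_)), c(1, 2, 4, 3))
  list(out = out, X = X, in_dim = d)
}

conv_backward <- function(d_out, cache, Wm) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  F_ <- dim(d_out)[3]
  dZ <- matrix(aperm(d_out, c(1, 2, 4, 3)), H * W * N, F_)
  dW <- crossprod(cache$X, dZ)
  db <- colSums(dZ)
  dXc <- dZ %*% t(Wm)
  dP <- array(0, c(H + 2, W + 2, C, N))
  k <- 0L
  for (ci in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    dP[dy + seq_len(H), dx + seq_len(W), ci, ] <-
      dP[dy + seq_len(H), dx + seq_len(W), ci, , drop = FALSE] +
      array(dXc[, k], c(H, W, 1, N))
  }
  list(dx = dP[2:(H + 1), 2:(W + 1), , , drop = FALSE], dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, W, 2); ce <- seq(2, W, 2)
  a <- x[ro, co, , , drop = FALSE]; b <- x[re, co, , , drop = FALSE]
  cc <- x[ro, ce, , , drop = FALSE]; dd <- x[re, ce, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, a = a, b = b, cc = cc, dd = dd, in_dim = d)
}

pool_backward <- function(d_out, cache) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, W, 2); ce <- seq(2, W, 2)
  out <- pmax(cache$a, cache$b, cache$cc, cache$dd)
  dx <- array(0, d)
  dx[ro, co, , ] <- d_out * (cache$a == out)
  dx[re, co, , ] <- d_out * (cache$b == out)
  dx[ro, ce, , ] <- d_out * (cache$cc == out)
  dx[re, ce, , ] <- d_out * (cache$dd == out)
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam optimizer state and update (beta1 0.9, beta2 0.999, eps 1e-8).
adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g * g
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
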