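# Minimal neural-network core: 3x3 and 1x1 convolutions, batch norm, ReLU,
# 2x2 max pooling, bilinear 2x upsampling, softmax cross-entropy and Adam.
# Activations are stored as (H, W, N, C) arrays: with channels last, a
# channel contraction is a single matrix product on matrix(x, ncol = C),
# which keeps every layer a handful of BLAS calls.  Backward passes are
# hand-derived and verified by finite-difference gradient checks in the
# test suite.

act4d <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  array(x, d)
}

conv3x3_forward <- function(X, W, b) {
  d <- dim(X)
  H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  Xp <- array(0, c(H + 2L, Wd + 2L, N, Cin))
  Xp[2:(H + 1), 2:(Wd + 1), , ] <- X
  Ymat <- matrix(rep(b, each = H * Wd * N), H * Wd * N, Cout)
  for (di in 0:2) {
    for (dj in 0:2) {
      Xs <- Xp[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE]
      dim(Xs) <- c(H * Wd * N, Cin)
      Wk <- matrix(W[di + 1L, dj + 1L, , ], Cin, Cout)
      Ymat <- Ymat + Xs %*% Wk
    }
  }
  list(out = array(Ymat, c(H, Wd, N, Cout)), Xp = Xp)
}

conv3x3_backward <- function(dY, Xp, W) {
  dp <- dim(Xp)
  H <- dp[1] - 2L; Wd <- dp[2] - 2L; N <- dp[3]; Cin <- dp[4]
  Cout <- dim(W)[4]
  dYmat <- dY
  dim(dYmat) <- c(H * Wd * N, Cout)
  dW <- array(0, dim(W))
  for (di in 0:2) {
    for (dj in 0:2) {
      Xs <- Xp[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE]
      dim(Xs) <- c(H * Wd * N, Cin)
      dW[di + 1L, dj + 1L, , ] <- crossprod(Xs, dYmat)
    }
  }
  # adjoint of same-padding convolution: convolve dY with the spatially
  # flipped, channel-transposed kernel
  Wt <- aperm(W[3:1, 3:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  dX <- conv3x3_forward(dY, Wt, numeric(Cin))$out
  list(dX = dX, dW = dW, db = colSums(dYmat))
}

conv1x1_forward <- function(X, W, b) {
  d <- dim(X)
  Cout <- ncol(W)
  Ymat <- matrix(X, ncol = d[4]) %*% W
  Ymat <- Ymat + rep(b, each = nrow(Ymat))
  list(out = array(Ymat, c(d[1], d[2], d[3], Cout)), X = X)
}

conv1x1_backward <- function(dY, X, W) {
  d <- dim(X)
  dYmat <- matrix(dY, ncol = ncol(W))
  Xm <- matrix(X, ncol = d[4])
  list(dX = array(tcrossprod(dYmat, W), d),
       dW = crossprod(Xm, dYmat), db = colSums(dYmat))
}

BN_EPS <- 1e-5

bn_forward <- function(X, gamma, beta, running, training, momentum = 0.1) {
  d <- dim(X)
  C <- d[4]
  Xm <- matrix(X, ncol = C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- (Xm - rep(mu, each = nrow(Xm))) * rep(inv, each = nrow(Xm))
  out <- xhat * rep(gamma, each = nrow(Xm)) + rep(beta, each = nrow(Xm))
  list(out = array(out, d), xhat = xhat, inv = inv, running = running)
}

bn_backward <- function(dY, cache, gamma) {
  d <- dim(dY)
  n <- prod(d[1:3])
  dYm <- matrix(dY, ncol = d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(gamma, each = n)
  dXm <- (dxhat - rep(colMeans(dxhat), each = n) -
          xhat * rep(colMeans(dxhat * xhat), each = n)) *
    rep(cache$inv, each = n)
  list(dX = array(dXm, d), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

relu_backward <- function(dY, mask) dY * mask

maxpool2_forward <- function(X) {
  d <- dim(X)
  H <- d[1]; Wd <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, Wd, 2L)
  a <- X[io, jo, , , drop = FALSE]
  b <- X[io + 1L, jo, , , drop = FALSE]
  cc <- X[io, jo + 1L, , , drop = FALSE]
  dd <- X[io + 1L, jo + 1L, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out,
       masks = list(a == out, b == out & a != out,
                    cc == out & a != out & b != out,
                    dd == out & a != out & b != out & cc != out))
}

maxpool2_backward <- function(dY, masks, dimX) {
  H <- dimX[1]; Wd <- dimX[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, Wd, 2L)
  dX <- array(0, dimX)
  dX[io, jo, , ] <- dY * masks[[1]]
  dX[io + 1L, jo, , ] <- dY * masks[[2]]
  dX[io, jo + 1L, , ] <- dY * masks[[3]]
  dX[io + 1L, jo + 1L, , ] <- dY * masks[[4]]
  dX
}

# 2x bilinear upsampling as a pair of dense interpolation operators, so the
# backward pass is exactly the transpose.
upsample2_forward <- function(X) {
  d <- dim(X)
  R <- interp_matrix(2L * d[1], d[1])
  Cm <- interp_matrix(2L * d[2], d[2])
  Y1 <- array(R %*% matrix(X, nrow = d[1]), c(2L * d[1], d[2], d[3], d[4]))
  Y1p <- aperm(Y1, c(2L, 1L, 3L, 4L))
  Y2 <- array(Cm %*% matrix(Y1p, nrow = d[2]),
              c(2L * d[2], 2L * d[1], d[3], d[4]))
  aperm(Y2, c(2L, 1L, 3L, 4L))
}

upsample2_backward <- function(dY, dimX) {
  R <- interp_matrix(2L * dimX[1], dimX[1])
  Cm <- interp_matrix(2L * dimX[2], dimX[2])
  dYp <- aperm(dY, c(2L, 1L, 3L, 4L))
  d1 <- array(crossprod(Cm, matrix(dYp, nrow = 2L * dimX[2])),
              c(dimX[2], 2L * dimX[1], dimX[3], dimX[4]))
  d1p <- aperm(d1, c(2L, 1L, 3L, 4L))
  array(crossprod(R, matrix(d1p, nrow = 2L * dimX[1])), dimX)
}

concat_channels <- function(parts) {
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[4], integer(1))
  array(unlist(parts, use.names = FALSE), c(d[1], d[2], d[3], sum(cs)))
}

split_channels <- function(dX, widths) {
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- dX[, , , at + seq_len(widths[i]), drop = FALSE]
    at <- at + widths[i]
  }
  out
}

# Softmax cross-entropy over the channel dimension; labels are 0-based
# integers of shape (H, W, N).  Returns mean loss and dlogits.
softmax_xent <- function(logits, labels) {
  d <- dim(logits)
  K <- d[4]
  Z <- matrix(logits, ncol = K)
  P <- softmax_rows(Z)
  idx <- cbind(seq_len(nrow(P)), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, dlogits = array(G / nrow(P), d), probs = P)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Learning rate under the step-decay schedule
#'
#' The optimizers in this package use Adam with an initial learning rate
#' decayed by a fixed factor every `every` epochs: during epochs 1..25 the
#' default schedule yields 0.001, during epochs 26..50 it yields 0.0001,
#' and so on.
#'
#' @param epoch 1-based epoch index.
#' @param lr0 Initial learning rate.
#' @param factor Decay factor.
#' @param every Epochs between decays.
#'
#' @return The effective learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, lr0 = 1e-3, factor = 0.1, every = 25L) {
  assert_that(epoch >= 1, "epoch must be >= 1")
  lr0 * factor^((epoch - 1L) %/% every)
}
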