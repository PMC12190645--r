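# Internal numerical helpers shared across modules.

stop_cropdx <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cropdx_error"))
}

assert_that <- function(cond, msg, class = "cropdx_validation_error") {
  if (!isTRUE(cond)) stop_cropdx(msg, class)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
is_image <- function(x) {
  is.numeric(x) && (length(dim(x)) %in% c(2L, 3L))
}

# ITU-R 601 luma; accepts (H,W) or (H,W,3).
luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Derive a child seed from a master seed and a counter so per-item streams
# are order-independent.  Kept below 2^31 - 1 (R integers are 32 bit).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 104729 * as.double(index)) %% 2147483647)
}

# Replicate (Neumann) padding of a matrix by `r` pixels on every side.
pad_replicate <- function(I, r = 1L) {
  n <- nrow(I)
  m <- ncol(I)
  ri <- c(rep(1L, r), seq_len(n), rep(n, r))
  ci <- c(rep(1L, r), seq_len(m), rep(m, r))
  I[ri, ci, drop = FALSE]
}

# 3x3 Laplacian (4-neighbour stencil) with replicate borders.
laplacian3 <- function(I) {
  n <- nrow(I)
  m <- ncol(I)
  Ip <- pad_replicate(I, 1L)
  Ip[1:n, 2:(m + 1)] + Ip[3:(n + 2), 2:(m + 1)] +
    Ip[2:(n + 1), 1:m] + Ip[2:(n + 1), 3:(m + 2)] - 4 * I
}

# Box mean over a (w x w) window, replicate borders.
box_mean <- function(I, w) {
  r <- (w - 1L) %/% 2L
  n <- nrow(I)
  m <- ncol(I)
  Ip <- pad_replicate(I, r)
  s <- matrix(0, n, m)
  for (di in 0:(w - 1L)) {
    for (dj in 0:(w - 1L)) {
      s <- s + Ip[di + seq_len(n), dj + seq_len(m)]
    }
  }
  s / (w * w)
}

# Dense 1-D linear interpolation operator mapping n_in samples to n_out,
# with half-pixel centre alignment and edge clamping.  Used both for image
# resizing and as the (exactly transposable) upsampling step inside the
# segmentation network.
interp_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    M[, 1] <- 1
    return(M)
  }
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  i0 <- floor(pos)
  w1 <- pos - i0
  i0 <- as.integer(i0)
  i1 <- pmin(i0 + 1L, n_in - 1L)
  for (k in seq_len(n_out)) {
    M[k, i0[k] + 1L] <- M[k, i0[k] + 1L] + (1 - w1[k])
    M[k, i1[k] + 1L] <- M[k, i1[k] + 1L] + w1[k]
  }
  M
}

# Bilinear resize of a matrix or (H,W,C) array.
resize_bilinear <- function(img, h_out, w_out) {
  d <- dim(img)
  if (d[1] == h_out && d[2] == w_out) return(img)
  R <- interp_matrix(h_out, d[1])
  C <- interp_matrix(w_out, d[2])
  if (length(d) == 2L) {
    R %*% img %*% t(C)
  } else {
    out <- array(0, c(h_out, w_out, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- R %*% img[, , k] %*% t(C)
    out
  }
}

# Numerically stable softmax over the columns-last dimension of a matrix
# (rows = cases, cols = classes).
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

fmt_pct <- function(x) round(100 * x, 1)
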