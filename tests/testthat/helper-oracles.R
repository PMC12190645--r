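# Brute-force scalar-loop oracles, kept deliberately independent of the
# package's vectorized implementations, plus small phantom builders shared
# across test files.

# two-region step phantom with an optional second (quadrant) edge
step_phantom <- function(size = 64, lo = 0.1, hi = 0.9, quadrant = FALSE) {
  img <- matrix(lo, size, size)
  img[, (size %/% 2 + 1):size] <- hi
  if (quadrant) {
    rows <- (size %/% 2 + 1):size
    img[rows, ] <- lo + hi - img[rows, ]
  }
  img
}

# windowed variance by explicit loops with replicate padding
oracle_local_variance <- function(I, w) {
  r <- (w - 1) / 2
  n <- nrow(I); m <- ncol(I)
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      vals <- c()
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), n)
          jj <- min(max(j + dj, 1), m)
          vals <- c(vals, I[ii, jj])
        }
      }
      out[i, j] <- mean(vals^2) - mean(vals)^2
    }
  }
  out
}

# one linear-heat step (c = 1) with replicate borders, explicit loops
oracle_heat_step <- function(I, gamma) {
  n <- nrow(I); m <- ncol(I)
  out <- I
  for (i in 1:n) {
    for (j in 1:m) {
      up <- I[max(i - 1, 1), j]; down <- I[min(i + 1, n), j]
      left <- I[i, max(j - 1, 1)]; right <- I[i, min(j + 1, m)]
      out[i, j] <- I[i, j] + gamma * (up + down + left + right - 4 * I[i, j])
    }
  }
  out
}

# true convolution (index-reversed kernel) + bias sum + global average,
# quadruple loop
oracle_conv_feature <- function(I, w, b) {
  n <- nrow(I); m <- ncol(I)
  acc <- 0
  npos <- 0
  for (x in 1:(n - 2)) {
    for (y in 1:(m - 2)) {
      s <- 0
      for (r in 1:3) {
        for (cc in 1:3) {
          s <- s + I[x + 3 - r, y + 3 - cc] * w[r, cc]
        }
      }
      acc <- acc + s
      npos <- npos + 1
    }
  }
  acc / npos + sum(b)
}

# scalar-loop softmax
oracle_softmax <- function(z) {
  zm <- z - max(z)
  e <- exp(zm)
  e / sum(e)
}

# per-class confusion-matrix metrics, scalar loops
oracle_metrics <- function(pred, truth) {
  classes <- sort(unique(truth))
  precs <- recs <- f1s <- c()
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    precs <- c(precs, prec)
    recs <- c(recs, rec)
    f1s <- c(f1s, if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  }
  list(accuracy = mean(pred == truth), precision = mean(precs),
       recall = mean(recs), f1 = mean(f1s))
}

# pixel-loop segmentation metrics for a crisp prediction
oracle_seg_metrics <- function(pred_labels, truth) {
  acc <- mean(pred_labels == truth)
  ious <- c(); dices <- c()
  for (k in sort(unique(as.vector(truth)))) {
    inter <- 0; uni <- 0; psum <- 0; tsum <- 0; cross <- 0
    for (i in seq_along(truth)) {
      p <- pred_labels[i] == k
      t <- truth[i] == k
      if (p && t) inter <- inter + 1
      if (p || t) uni <- uni + 1
      psum <- psum + p
      tsum <- tsum + t
      if (p && t) cross <- cross + 1
    }
    ious <- c(ious, if (uni == 0) 1 else inter / uni)
    dices <- c(dices, 2 * cross / (psum + tsum))
  }
  list(accuracy = acc, mean_iou = mean(ious), fuzzy_overlap = mean(dices))
}

# small noiseless well-separated phantom spec used by several files
tiny_phantom_spec <- function(noise = 0, size = 32) {
  phantom_spec(image_size = size, n_classes = 3, noise_sigma = noise,
               lesion_count_range = c(2L, 2L),
               lesion_radius_range = c(4, 5), seed = 1L)
}
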