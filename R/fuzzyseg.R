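#' Gaussian membership parameters for one segmentation class
#'
#' @param center Centre `c` of the Gaussian membership on the 0--255
#'   intensity scale.
#' @param spread Spread `sigma` (> 0), same scale.
#'
#' @return An object of class `membership_params`.
#' @export
membership_params <- function(center, spread) {
  assert_that(length(center) == 1L && center >= 0 && center <= 255,
              "center must lie in [0, 255]")
  assert_that(length(spread) == 1L && spread > 0, "spread must be positive")
  structure(list(center = center, spread = spread), class = "membership_params")
}

#' Fit per-class membership parameters from ground-truth masks
#'
#' Estimates the centre and spread of each class's Gaussian membership as
#' the mean and standard deviation of the luminance (x255) of that class's
#' pixels over the training masks -- the histogram analysis that designs
#' the rule base.  A floor of 3 intensity levels keeps the spread positive
#' on noiseless renders.
#'
#' @param images List of images in `[0,1]`.
#' @param masks List of integer label masks.
#' @param n_classes Total number of segmentation classes.
#'
#' @return A list of [membership_params()], one per class `0..n_classes-1`.
#' @export
fit_membership_params <- function(images, masks, n_classes) {
  assert_that(length(images) == length(masks), "images/masks length mismatch")
  vals <- vector("list", n_classes)
  for (i in seq_along(images)) {
    lum <- luminance(images[[i]]) * 255
    m <- masks[[i]]
    for (k in seq_len(n_classes) - 1L) {
      sel <- m == k
      if (any(sel)) vals[[k + 1L]] <- c(vals[[k + 1L]], lum[sel])
    }
  }
  lapply(seq_len(n_classes), function(k) {
    v <- vals[[k]]
    if (is.null(v)) {
      # class absent from the training masks: flat, uninformative membership
      return(membership_params(127.5, 127.5))
    }
    membership_params(mean(v), max(stats::sd(v), 3, na.rm = TRUE))
  })
}

#' Gaussian membership degree
#'
#' `mu_A(x) = exp(-(x - c)^2 / (2 sigma^2))`: maximal (= 1) at the class
#' centre, `exp(-1/2)` one spread away.
#'
#' @param x Intensity or feature value(s).
#' @param p A [membership_params()] (or list with `center` and `spread`).
#'
#' @return Degree(s) in `(0, 1]`.
#' @export
gaussian_membership <- function(x, p) {
  assert_that(!is.null(p$spread) && p$spread > 0, "spread must be positive")
  exp(-(x - p$center)^2 / (2 * p$spread^2))
}

#' Mamdani min-implication
#'
#' Elementwise minimum of two membership degrees -- commutative,
#' idempotent and monotone in both arguments.
#'
#' @param mu_a,mu_b Degrees in `[0,1]` (scalars, vectors or arrays of a
#'   common shape).
#'
#' @return Elementwise `min(mu_a, mu_b)`.
#' @export
mamdani_implication <- function(mu_a, mu_b) {
  assert_that(all(mu_a >= 0 & mu_a <= 1) && all(mu_b >= 0 & mu_b <= 1),
              "membership degrees must lie in [0,1]")
  pmin(mu_a, mu_b)
}

#' Apply a Mamdani rule base to membership planes
#'
#' Every rule `(A, B) -> C` contributes
#' `min(planes_current[[A]], planes_prev[[B]])` to output class `C`;
#' multiple rules firing into the same consequent are aggregated by the
#' elementwise maximum (standard Mamdani aggregation).
#'
#' @param planes_current,planes_prev Named lists of same-shaped membership
#'   planes in `[0,1]` (antecedents at the current node and its
#'   predecessor).
#' @param rules A data frame with character columns `a`, `b`, `c` naming
#'   antecedent and consequent classes; default: one rule per class
#'   `(A, A) -> A`.
#'
#' @return Named list of fused planes, one per consequent class.
#' @export
apply_fuzzy_rules <- function(planes_current, planes_prev, rules = NULL) {
  if (is.null(rules)) {
    rules <- data.frame(a = names(planes_current), b = names(planes_current),
                        c = names(planes_current))
  }
  known <- union(names(planes_current), names(planes_prev))
  bad <- setdiff(unique(c(rules$a, rules$b)), known)
  if (length(bad) > 0) {
    stop_cropdx(sprintf("rule references unknown class: %s",
                        paste(bad, collapse = ", ")), "cropdx_config_error")
  }
  out <- list()
  for (r in seq_len(nrow(rules))) {
    fired <- mamdani_implication(planes_current[[rules$a[r]]],
                                 planes_prev[[rules$b[r]]])
    key <- rules$c[r]
    out[[key]] <- if (is.null(out[[key]])) fired else pmax(out[[key]], fired)
  }
  out
}

#' Centroid (centre-of-area) defuzzification
#'
#' `COA = sum(x * mu(x)) / sum(mu(x))` over the discrete intensity domain
#' `x = 0..255`; always lies inside the convex hull of the support.
#'
#' @param mu_c Numeric vector of length 256: the aggregated membership over
#'   the intensity domain.
#'
#' @return The centre-of-area value.
#' @export
centroid_defuzzify <- function(mu_c) {
  assert_that(length(mu_c) == 256L, "mu_c must have one value per intensity 0..255")
  assert_that(all(mu_c >= 0), "memberships must be non-negative")
  s <- sum(mu_c)
  if (s <= 0) {
    stop_cropdx("centroid undefined for an all-zero membership",
                "cropdx_undefined_centroid_error")
  }
  sum((0:255) * mu_c) / s
}

#' Segment an image with a fuzzy U-Net++
#'
#' Runs the network forward, scores every top-row node of the skip lattice
#' with the shared class head, and fuses the evidence with Mamdani rules:
#' adjacent top-row nodes are combined pairwise by min-implication and
#' aggregated by max into network memberships; at the decision stage each
#' class's network membership is min-combined with its Gaussian intensity
#' membership.  Crisp labels are the per-pixel argmax of the fused class
#' memberships; a centre-of-area plane over the 0--255 intensity domain is
#' additionally emitted as the defuzzified intensity summary.
#'
#' @param image Matrix or RGB array in `[0,1]` whose size is divisible by
#'   `2^(depth-1)`.
#' @param model A trained (or initialized) `unetpp_model`.
#' @param mp List of [membership_params()], one per segmentation class; if
#'   `NULL`, only network memberships are used.
#'
#' @return An object of class `segmentation_map`: list with `memberships`
#'   (`H x W x n_classes` array in `[0,1]`), `labels` (`H x W` integer
#'   matrix, 0-based) and `coa` (`H x W` centre-of-area plane).
#' @export
segment <- function(image, model, mp = NULL) {
  assert_that(inherits(model, "unetpp_model"), "model must be a unetpp_model")
  cfg <- model$cfg
  X <- if (cfg$in_channels == 1L) act4d(luminance(image)) else act4d(image)
  fwd <- unetpp_forward(model, X, training = FALSE)
  d <- dim(X)
  K <- cfg$n_classes
  npx <- d[1] * d[2]
  probs_of <- function(logits) softmax_rows(matrix(logits, ncol = K))
  scores <- lapply(fwd$row0_logits, probs_of)  # one (npx x K) matrix per node
  L <- length(scores)
  final <- scores[[L]]
  if (L >= 2L) {
    fused <- matrix(0, npx, K)
    for (j in 2:L) {
      fused <- pmax(fused, pmin(scores[[j]], scores[[j - 1L]]))
    }
    net_mem <- pmax(final, fused)
  } else {
    net_mem <- final
  }
  if (!is.null(mp)) {
    assert_that(length(mp) == K, "need one membership_params per class")
    lum255 <- as.vector(luminance(image)) * 255
    g <- vapply(mp, function(p) gaussian_membership(lum255, p),
                numeric(npx))
    mem <- pmin(net_mem, g)
    # centre-of-area of the aggregated output fuzzy set over intensity
    Gx <- vapply(mp, function(p) gaussian_membership(0:255, p), numeric(256))
    num <- rep(0, npx)
    den <- rep(0, npx)
    agg <- matrix(0, npx, 256)
    for (k in seq_len(K)) {
      agg <- pmax(agg, outer(mem[, k], Gx[, k], pmin))
    }
    den <- rowSums(agg)
    num <- agg %*% (0:255)
    coa <- matrix(ifelse(den > 0, num / den, 127.5), d[1], d[2])
  } else {
    mem <- net_mem
    coa <- (matrix(max.col(mem, ties.method = "first"), d[1], d[2]) - 1) *
      (255 / (K - 1))
  }
  labels <- matrix(max.col(mem, ties.method = "first") - 1L, d[1], d[2])
  structure(list(memberships = array(mem, c(d[1], d[2], K)),
                 labels = labels, coa = coa),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %dx%d px, %d classes; label counts: %s\n",
              nrow(x$labels), ncol(x$labels), dim(x$memberships)[3],
              paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}

#' Train the fuzzy U-Net++ segmenter
#'
#' Minimizes the mean pixelwise softmax cross-entropy with Adam (initial
#' learning rate 0.001, decayed by 0.1 every 25 epochs -- see
#' [lr_schedule()]).
#'
#' @param dataset A `phantom_dataset` (or list with `images`, `masks`).
#' @param cfg A [unetpp_config()].
#' @param train_cfg List of training options: `epochs` (default 10),
#'   `batch_size` (4), `lr` (1e-3), `decay_every` (25), `decay_factor`
#'   (0.1).
#' @param seed Shuffling seed.
#'
#' @return A trained `unetpp_model` with `loss_history` (one mean loss per
#'   epoch).
#' @export
train_segmenter <- function(dataset, cfg, train_cfg = list(), seed = 1L) {
  assert_that(length(dataset$images) > 0, "dataset is empty")
  assert_that(length(dataset$masks) == length(dataset$images),
              "dataset must carry one mask per image")
  tc <- utils::modifyList(list(epochs = 10L, batch_size = 4L, lr = 1e-3,
                               decay_every = 25L, decay_factor = 0.1),
                          train_cfg)
  model <- build_unetpp(cfg)
  state <- adam_init(model$params)
  n <- length(dataset$images)
  to_x <- function(img) if (cfg$in_channels == 1L) luminance(img) else img
  losses <- numeric(tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_schedule(epoch, tc$lr, tc$decay_factor, tc$decay_every)
    ord <- withr::with_seed(derive_seed(seed, epoch), sample.int(n))
    batch_losses <- c()
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      xs <- lapply(dataset$images[idx], to_x)
      X <- concat_samples(xs, cfg$in_channels)
      labels <- array(unlist(dataset$masks[idx], use.names = FALSE),
                      c(dim(X)[1], dim(X)[2], length(idx)))
      fwd <- unetpp_forward(model, X, training = TRUE)
      model <- fwd$model
      # labels interleave with the channel-last layout via replication
      sx <- softmax_xent_pixels(fwd$logits, labels)
      grads <- unetpp_backward(model, fwd, sx$dlogits)
      upd <- adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      batch_losses <- c(batch_losses, sx$loss)
    }
    losses[epoch] <- mean(batch_losses)
  }
  model$loss_history <- losses
  model$trained <- TRUE
  model
}

# Stack single images (H,W) or (H,W,C) into the (H,W,N,C) layout.
concat_samples <- function(xs, in_channels) {
  d <- dim(xs[[1]])
  H <- d[1]; W <- d[2]
  N <- length(xs)
  X <- array(0, c(H, W, N, in_channels))
  for (i in seq_len(N)) {
    if (in_channels == 1L) X[, , i, 1] <- xs[[i]]
    else for (ch in seq_len(in_channels)) X[, , i, ch] <- xs[[i]][, , ch]
  }
  X
}

# Cross-entropy where logits are (H,W,N,K) and labels (H,W,N).
softmax_xent_pixels <- function(logits, labels) {
  softmax_xent(logits, labels)
}

#' Segmentation quality metrics
#'
#' Pixel accuracy, mean intersection-over-union over the classes present in
#' the truth, and a fuzzy overlap score: the soft Dice coefficient between
#' the predicted membership planes and the one-hot truth, averaged over
#' classes present.
#'
#' @param pred A `segmentation_map` (or a plain label matrix, in which case
#'   crisp memberships are assumed).
#' @param truth Integer label matrix of the same size.
#' @param n_classes Total class count (defaults to what `pred` carries).
#'
#' @return A tibble with columns `accuracy`, `mean_iou`, `fuzzy_overlap`.
#' @export
segmentation_metrics <- function(pred, truth, n_classes = NULL) {
  if (inherits(pred, "segmentation_map")) {
    labels <- pred$labels
    mem <- pred$memberships
    if (is.null(n_classes)) n_classes <- dim(mem)[3]
  } else {
    labels <- pred
    if (is.null(n_classes)) n_classes <- max(labels, truth) + 1L
    mem <- array(0, c(nrow(labels), ncol(labels), n_classes))
    for (k in seq_len(n_classes) - 1L) mem[, , k + 1L] <- (labels == k) * 1
  }
  assert_that(identical(dim(labels), dim(truth)),
              "prediction and truth must have the same shape")
  assert_that(max(truth) < n_classes && min(truth) >= 0,
              "truth labels outside the configured classes")
  acc <- mean(labels == truth)
  present <- sort(unique(as.vector(truth)))
  ious <- vapply(present, function(k) {
    inter <- sum(labels == k & truth == k)
    uni <- sum(labels == k | truth == k)
    if (uni == 0) 1 else inter / uni
  }, numeric(1))
  dices <- vapply(present, function(k) {
    m <- mem[, , k + 1L]
    t1 <- (truth == k) * 1
    (2 * sum(m * t1)) / (sum(m) + sum(t1))
  }, numeric(1))
  tibble::tibble(accuracy = acc, mean_iou = mean(ious),
                 fuzzy_overlap = mean(dices))
}
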