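#' Configuration of the gorilla/remora feature selector
#'
#' @param population Number of gorillas (candidate feature subsets), >= 2;
#'   default 50.
#' @param generations Number of generations; default 100.
#' @param alpha Weight of holdout accuracy in the fitness; default 1.
#' @param beta Weight of the redundancy penalty; default 0.3.
#' @param attach_schedule Function of the 0--1 generation fraction giving
#'   the probability of a remora attachment event; the default decays
#'   linearly from 1.0 to 0.1 so early generations explore and late ones
#'   exploit.
#' @param seed RNG seed.
#'
#' @return An object of class `mgra_config`.
#' @export
mgra_config <- function(population = 50L, generations = 100L,
                        alpha = 1.0, beta = 0.3,
                        attach_schedule = function(frac) 0.9 * (1 - frac) + 0.1,
                        seed = 1L) {
  assert_that(population >= 2, "population must be >= 2")
  assert_that(generations >= 0, "generations must be >= 0")
  assert_that(alpha >= 0 && beta >= 0 && alpha + beta > 0,
              "alpha, beta must be >= 0 with alpha + beta > 0")
  assert_that(is.function(attach_schedule), "attach_schedule must be a function")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 alpha = alpha, beta = beta,
                 attach_schedule = attach_schedule, seed = as.integer(seed)),
            class = "mgra_config")
}

#' Bank of 3x3 convolution kernels for feature extraction
#'
#' The first eight kernels are standard edge/texture operators (identity,
#' box mean, Sobel pair, 4- and 8-neighbour Laplacians, emboss, sharpen);
#' the remainder are seeded unit-norm Gaussian kernels.  All biases are
#' zero by default.
#'
#' @param m Number of kernels (>= 1); default 64.
#' @param seed Seed for the random kernels.
#'
#' @return List with `weights` (`3 x 3 x m` array) and `biases`
#'   (`3 x 3 x m` array of per-tap biases).
#' @export
kernel_bank <- function(m = 64L, seed = 1L) {
  assert_that(m >= 1, "need at least one kernel")
  fixed <- list(
    matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3),
    matrix(1 / 9, 3, 3),
    matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
    matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3),
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3),
    matrix(c(-2, -1, 0, -1, 1, 1, 0, 1, 2), 3, 3),
    matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
  )
  W <- array(0, c(3, 3, m))
  n_fixed <- min(m, length(fixed))
  for (k in seq_len(n_fixed)) W[, , k] <- fixed[[k]]
  if (m > n_fixed) {
    withr::with_seed(as.integer(seed), {
      for (k in (n_fixed + 1L):m) {
        kk <- matrix(rnorm(9), 3, 3)
        W[, , k] <- kk / sqrt(sum(kk^2))
      }
    })
  }
  list(weights = W, biases = array(0, c(3, 3, m)))
}

#' Convolutional summary features of a segmented image
#'
#' True 3x3 convolution (kernel index-reversed relative to
#' cross-correlation) of each kernel over the image at stride 1 on valid
#' positions, plus the summed per-tap bias, followed by global average
#' pooling -- one scalar feature per kernel.
#'
#' @param image Single-channel matrix (use the lesion-masked luminance of a
#'   segmented image) at least 3x3.
#' @param bank A [kernel_bank()] (or list with `weights`, `biases`).
#'
#' @return Numeric feature vector of length `dim(bank$weights)[3]`.
#' @export
conv_features <- function(image, bank = kernel_bank()) {
  assert_that(is.matrix(image), "image must be a single-channel matrix")
  assert_that(nrow(image) >= 3 && ncol(image) >= 3,
              "kernel larger than image")
  H <- nrow(image)
  W <- ncol(image)
  m <- dim(bank$weights)[3]
  Ho <- H - 2L
  Wo <- W - 2L
  feats <- numeric(m)
  # accumulate sum over all valid positions of the flipped-kernel response
  slices <- vector("list", 9L)
  idx <- 1L
  for (di in 0:2) {
    for (dj in 0:2) {
      slices[[idx]] <- sum(image[di + seq_len(Ho), dj + seq_len(Wo)])
      idx <- idx + 1L
    }
  }
  # For global-average pooling only the per-offset sums are needed:
  # mean over positions of sum_rc I(x+2-r, y+2-c) w(r,c) re-indexes to the
  # slice at offset (2-r, 2-c).
  svec <- unlist(slices)
  for (k in seq_len(m)) {
    wk <- bank$weights[, , k]
    acc <- 0
    idx <- 1L
    for (di in 0:2) {
      for (dj in 0:2) {
        # offset (di,dj) pairs with flipped kernel tap (3-di, 3-dj)
        acc <- acc + svec[idx] * wk[3L - di, 3L - dj]
        idx <- idx + 1L
      }
    }
    feats[k] <- acc / (Ho * Wo) + sum(bank$biases[, , k])
  }
  feats
}

#' Gorilla position update
#'
#' `X_new = X_best + STOCH * (X_best - X_current)` with a single scalar
#' `STOCH ~ Uniform(0,1)` per update, clipped to `[0,1]` coordinatewise.
#'
#' @param current,best Numeric coordinate vectors in `[0,1]^M`.
#' @param stoch Optional fixed stochastic multiplier (drawn uniformly when
#'   `NULL`).
#'
#' @return The updated coordinate vector.
#' @export
gorilla_update <- function(current, best, stoch = NULL) {
  assert_that(length(current) == length(best), "dimension mismatch")
  if (is.null(stoch)) stoch <- runif(1)
  clip01(best + stoch * (best - current))
}

#' Remora attachment strength
#'
#' Normalized mean absolute deviation of the host's coordinates:
#' `f(d) = (1 / 0.5) * sum(|X_i - mean(X)|) / N`, lying in `[0,1]` (0 for a
#' uniform host, 1 for coordinates split between 0 and 1).
#'
#' @param host Numeric coordinate vector in `[0,1]^M`.
#'
#' @return Scalar in `[0,1]`.
#' @export
attachment_strength <- function(host) {
  assert_that(length(host) >= 1, "empty position")
  min(mean(abs(host - mean(host))) / 0.5, 1)
}

#' Remora position update
#'
#' `X_adaptive = X_host + f(d) * (X_best - X_host)` with
#' `f(d) = attachment_strength(host)`: a convex step from host toward the
#' best position, so in-range inputs need no clipping.
#'
#' @param host,best Numeric coordinate vectors in `[0,1]^M`.
#'
#' @return The adapted coordinate vector.
#' @export
remora_update <- function(host, best) {
  assert_that(length(host) == length(best), "dimension mismatch")
  f <- attachment_strength(host)
  host + f * (best - host)
}

#' Redundancy of a feature subset
#'
#' Mean absolute pairwise Pearson correlation among the selected feature
#' columns; 0 for a single feature.  A pair involving a zero-variance
#' column is treated as maximally redundant (correlation 1).
#'
#' @param features Numeric matrix (rows = samples) of the *selected*
#'   columns.
#'
#' @return Scalar in `[0,1]`.
#' @export
redundancy <- function(features) {
  features <- as.matrix(features)
  assert_that(ncol(features) >= 1, "need at least one selected feature")
  if (ncol(features) == 1L) return(0)
  assert_that(nrow(features) >= 2, "need at least two samples")
  sds <- apply(features, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(features))
  cm[!is.finite(cm)] <- 1  # zero-variance columns: maximally redundant
  vals <- abs(cm[upper.tri(cm)])
  mean(vals)
}

#' Build the evaluation bundle for wrapper fitness
#'
#' Fixes a stratified 70/30 split of the feature table once so every
#' fitness evaluation is deterministic and comparable.
#'
#' @param features Numeric matrix, rows = samples, columns = candidate
#'   features.
#' @param labels Class labels (one per row).
#' @param seed Split seed.
#' @param fraction Training fraction.
#'
#' @return List with `features`, `labels`, `train_idx`, `test_idx`.
#' @export
make_eval_bundle <- function(features, labels, seed = 1L, fraction = 0.7) {
  features <- as.matrix(features)
  labels <- as.vector(labels)
  assert_that(nrow(features) == length(labels), "features/labels mismatch")
  assert_that(length(unique(labels)) >= 2,
              "fitness needs at least two classes")
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(labels), labels), function(ix) {
      n_tr <- max(1L, round(fraction * length(ix)))
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(features = features, labels = labels,
       train_idx = sort(train_idx),
       test_idx = setdiff(seq_along(labels), train_idx))
}

# Nearest class-centroid classifier on standardized columns: the fast
# reference classifier inside the wrapper fitness.
nearest_centroid_accuracy <- function(features, labels, train_idx, test_idx) {
  mu <- colMeans(features[train_idx, , drop = FALSE])
  sdv <- apply(features[train_idx, , drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")
  classes <- sort(unique(labels[train_idx]))
  cents <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(Z[train_idx[labels[train_idx] == cl], , drop = FALSE])
  }))
  d2 <- outer(rowSums(Z[test_idx, , drop = FALSE]^2), rowSums(cents^2), "+") -
    2 * Z[test_idx, , drop = FALSE] %*% t(cents)
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == labels[test_idx])
}

selected_indices <- function(coords) which(coords > 0.5)

#' Wrapper fitness of a candidate feature subset
#'
#' `J(F) = alpha * Accuracy(F) - beta * Redundancy(F)`, where accuracy is
#' the holdout accuracy of a nearest class-centroid classifier on the
#' selected columns and redundancy is [redundancy()].  An empty subset
#' receives the sentinel `-Inf`.
#'
#' @param position Coordinate vector in `[0,1]^M` (subset = coordinates
#'   `> 0.5`), or an integer-typed vector of selected column indices.
#' @param bundle A [make_eval_bundle()].
#' @param cfg An [mgra_config()] (supplies `alpha`, `beta`).
#'
#' @return Scalar fitness `J`.
#' @export
fitness <- function(position, bundle, cfg = mgra_config()) {
  sel <- if (is.integer(position)) position else selected_indices(position)
  if (length(sel) == 0L) return(-Inf)
  assert_that(length(unique(bundle$labels)) >= 2,
              "fitness needs at least two classes")
  acc <- nearest_centroid_accuracy(bundle$features[, sel, drop = FALSE],
                                   bundle$labels, bundle$train_idx,
                                   bundle$test_idx)
  red <- redundancy(bundle$features[, sel, drop = FALSE])
  cfg$alpha * acc - cfg$beta * red
}

#' Select features with the moving gorilla/remora metaheuristic
#'
#' Maintains a population of continuous positions in `[0,1]^M` (a feature
#' is selected when its coordinate exceeds 0.5).  Each generation every
#' member takes a gorilla step toward the best-so-far position; with a
#' probability given by the attachment schedule one random member is then
#' replaced by a remora step from a random host toward the best.  The best
#' position is elitist, so the best-fitness history is non-decreasing.
#'
#' @param features Numeric matrix, rows = samples, columns = features
#'   (M >= 2).
#' @param labels Class labels, >= 2 classes.
#' @param cfg An [mgra_config()].
#'
#' @return An object of class `mgra_result`: list with `selected` (sorted
#'   indices), `best_coords`, `best_fitness`, `history` (length
#'   `generations + 1`), `initial_count`, `selected_count`,
#'   `selection_ratio` and `cfg`.
#' @export
select_features <- function(features, labels, cfg = mgra_config()) {
  features <- as.matrix(features)
  M <- ncol(features)
  assert_that(M >= 2, "need at least two candidate features")
  bundle <- make_eval_bundle(features, labels, seed = derive_seed(cfg$seed, 0L))
  withr::with_seed(cfg$seed, {
    pop <- matrix(runif(cfg$population * M), cfg$population, M)
    fits <- apply(pop, 1L, fitness, bundle = bundle, cfg = cfg)
    if (all(!is.finite(fits))) {
      # degenerate start (all-empty subsets): force one full candidate
      pop[1L, ] <- 1
      fits[1L] <- fitness(pop[1L, ], bundle, cfg)
    }
    best_i <- which.max(fits)
    best <- pop[best_i, ]
    best_fit <- fits[best_i]
    history <- numeric(cfg$generations + 1L)
    history[1L] <- best_fit
    for (t in seq_len(cfg$generations)) {
      for (p in seq_len(cfg$population)) {
        pop[p, ] <- gorilla_update(pop[p, ], best)
      }
      if (runif(1) < cfg$attach_schedule(t / max(cfg$generations, 1L))) {
        host <- pop[sample.int(cfg$population, 1L), ]
        pop[sample.int(cfg$population, 1L), ] <- remora_update(host, best)
      }
      fits <- apply(pop, 1L, fitness, bundle = bundle, cfg = cfg)
      gen_best <- which.max(fits)
      if (is.finite(fits[gen_best]) && fits[gen_best] > best_fit) {
        best_fit <- fits[gen_best]
        best <- pop[gen_best, ]
      }
      history[t + 1L] <- best_fit
    }
  })
  sel <- selected_indices(best)
  structure(list(selected = sel, best_coords = best, best_fitness = best_fit,
                 history = history, initial_count = M,
                 selected_count = length(sel),
                 selection_ratio = selection_ratio(M, length(sel)),
                 cfg = cfg),
            class = "mgra_result")
}

#' @export
print.mgra_result <- function(x, ...) {
  cat(sprintf("<mgra_result> %d/%d features selected (%.1f%%), best J = %.4f\n",
              x$selected_count, x$initial_count, x$selection_ratio,
              x$best_fitness))
  invisible(x)
}

#' Planted feature-selection benchmark problem
#'
#' Generates a feature table in which only the first `n_informative`
#' columns carry class signal and each of them is individually necessary:
#' class 0 is a baseline and class `i` (for `i = 1..n_informative`) shifts
#' exactly informative feature `i` by `effect`, so dropping any informative
#' feature merges two classes.  The remaining columns are pure noise.
#'
#' @param n_samples Number of rows.
#' @param n_features Total feature count.
#' @param n_informative Number of informative features (default 3, giving
#'   `n_informative + 1` classes).
#' @param effect Mean shift of the informative features (in noise SDs).
#' @param seed RNG seed.
#'
#' @return List with `features` (matrix), `labels` (0-based) and
#'   `informative` (column indices).
#' @export
planted_feature_problem <- function(n_samples = 150L, n_features = 20L,
                                    n_informative = 3L, effect = 2.5,
                                    seed = 1L) {
  assert_that(n_features > n_informative, "need more features than informative")
  withr::with_seed(as.integer(seed), {
    labels <- rep(0:n_informative, length.out = n_samples)
    X <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
    for (i in seq_len(n_informative)) {
      X[labels == i, i] <- X[labels == i, i] + effect
    }
  })
  list(features = X, labels = labels, informative = seq_len(n_informative))
}

#' Feature selection ratio
#'
#' `100 * selected / initial`, reported to one decimal place.
#'
#' @param initial Initial feature count (>= 1).
#' @param selected Selected feature count (`0 <= selected <= initial`).
#'
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' selection_ratio(1024, 248)  # 24.2
selection_ratio <- function(initial, selected) {
  assert_that(initial >= 1, "initial must be >= 1")
  assert_that(selected >= 0 && selected <= initial,
              "selected must lie in 0..initial")
  round(100 * selected / initial, 1)
}
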