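#' Configuration of the graph-based LeNet classifier
#'
#' @param n_layers Number of graph-convolution layers (>= 1); default 3.
#' @param widths Output width per layer; default `c(16, 32, 64)`.
#' @param edge_threshold Cosine-similarity cutoff for creating an edge;
#'   default 0.5.
#' @param n_classes Number of disease classes.
#' @param node_identity Append a one-hot node-identity encoding to each
#'   node's scalar feature signal (default `TRUE`).  With purely scalar
#'   signals and weights shared across nodes, the network is almost
#'   invariant to node permutations, so it cannot learn *which* feature
#'   carries a class difference; the identity channels restore node
#'   awareness while leaving the propagation rule unchanged.
#' @param seed Initialization seed.
#'
#' @return An object of class `glnp_config`.
#' @export
glnp_config <- function(n_layers = 3L, widths = c(16L, 32L, 64L),
                        edge_threshold = 0.5, n_classes = 3L,
                        node_identity = TRUE, seed = 1L) {
  assert_that(n_layers >= 1, "n_layers must be >= 1")
  assert_that(length(widths) == n_layers, "length(widths) must equal n_layers")
  assert_that(edge_threshold >= 0 && edge_threshold <= 1,
              "edge_threshold must lie in [0,1]")
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  structure(list(n_layers = as.integer(n_layers), widths = as.integer(widths),
                 edge_threshold = edge_threshold,
                 n_classes = as.integer(n_classes),
                 node_identity = isTRUE(node_identity),
                 seed = as.integer(seed)),
            class = "glnp_config")
}

#' Cosine similarity of two vectors
#'
#' @param v_i,v_j Non-zero numeric vectors of equal length.
#'
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(v_i, v_j) {
  assert_that(length(v_i) == length(v_j), "vectors must have equal length")
  ni <- sqrt(sum(v_i^2))
  nj <- sqrt(sum(v_j^2))
  if (ni == 0 || nj == 0) {
    stop_cropdx("cosine similarity undefined for a zero vector",
                "cropdx_undefined_similarity_error")
  }
  sum(v_i * v_j) / (ni * nj)
}

#' Build the feature-correlation graph
#'
#' Nodes are the selected features; feature `i`'s profile is its column of
#' values across the training images.  An undirected edge `(i, j)` with
#' weight `e_ij` exists iff the cosine similarity of the two profiles is at
#' least `edge_threshold` (anticorrelated features stay unconnected).
#' Self-loops enter only through `A' = A + I`; the symmetric normalized
#' propagation operator `D^(-1/2) A' D^(-1/2)` is precomputed.
#'
#' @param profiles Numeric matrix, rows = training images, columns =
#'   selected features (>= 2 columns).
#' @param cfg A [glnp_config()] (supplies `edge_threshold`).
#'
#' @return An object of class `feature_graph`: list with `adjacency` (A,
#'   zero diagonal), `adjacency_loops` (A'), `degree`, `prop` (the
#'   normalized operator) and `n_nodes`.
#' @export
build_graph <- function(profiles, cfg = glnp_config()) {
  profiles <- as.matrix(profiles)
  m <- ncol(profiles)
  assert_that(m >= 2, "need at least two features to build a graph")
  assert_that(all(is.finite(profiles)), "profiles must be finite")
  A <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      s <- cosine_similarity(profiles[, i], profiles[, j])
      if (s >= cfg$edge_threshold) {
        A[i, j] <- s
        A[j, i] <- s
      }
    }
  }
  Ap <- A + diag(m)
  deg <- rowSums(Ap)
  dinv <- 1 / sqrt(deg)
  prop <- Ap * outer(dinv, dinv)
  structure(list(adjacency = A, adjacency_loops = Ap, degree = deg,
                 prop = prop, n_nodes = m),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("<feature_graph> %d nodes, %d edges\n", x$n_nodes,
              sum(x$adjacency[upper.tri(x$adjacency)] != 0)))
  invisible(x)
}

#' Export a feature graph as an edge list
#'
#' @param graph A [build_graph()] result.
#'
#' @return A tibble with columns `node_i`, `node_j`, `weight`.
#' @export
graph_edge_list <- function(graph) {
  ij <- which(upper.tri(graph$adjacency) & graph$adjacency != 0, arr.ind = TRUE)
  tibble::tibble(node_i = ij[, 1], node_j = ij[, 2],
                 weight = graph$adjacency[ij])
}

#' One graph-convolution layer
#'
#' `H' = ReLU(D^(-1/2) A' D^(-1/2) H W)` with self-loops guaranteeing
#' strictly positive degrees.
#'
#' @param H Node feature matrix (rows = nodes).
#' @param graph A `feature_graph`.
#' @param W Weight matrix (input width x output width).
#' @param activation Either `"relu"` (default) or `"identity"`.
#'
#' @return The propagated node feature matrix.
#' @export
gcn_layer <- function(H, graph, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  H <- as.matrix(H)
  assert_that(nrow(H) == graph$n_nodes, "H rows must equal node count")
  assert_that(ncol(H) == nrow(W), "H/W shape mismatch")
  Z <- graph$prop %*% H %*% W
  if (activation == "relu") pmax(Z, 0) else Z
}

#' Max graph pooling
#'
#' Columnwise maximum over the node dimension: one graph-level vector.
#'
#' @param H_final Node feature matrix (>= 1 node).
#'
#' @return Numeric vector of length `ncol(H_final)`.
#' @export
graph_pool <- function(H_final) {
  H_final <- as.matrix(H_final)
  assert_that(nrow(H_final) >= 1, "empty graph")
  apply(H_final, 2L, max)
}

#' Softmax classification head
#'
#' `O = softmax(W z + b)` computed with the log-sum-exp shift, so extreme
#' logits do not overflow.
#'
#' @param z Graph embedding vector.
#' @param W Weight matrix (`n_classes x length(z)`).
#' @param b Bias vector (`n_classes`).
#'
#' @return Probability vector (positive, sums to 1).
#' @export
classify <- function(z, W, b) {
  assert_that(ncol(W) == length(z) && nrow(W) == length(b),
              "head dimensions disagree")
  logits <- as.vector(W %*% z + b)
  if (!all(is.finite(logits))) {
    stop_cropdx("non-finite logits", "cropdx_numeric_error")
  }
  as.vector(softmax_rows(matrix(logits, 1)))
}

glnp_init_params <- function(cfg, n_nodes) {
  in_width <- 1L + if (cfg$node_identity) n_nodes else 0L
  widths <- c(in_width, cfg$widths)
  params <- list()
  withr::with_seed(cfg$seed, {
    for (l in seq_len(cfg$n_layers)) {
      params[[paste0("W", l)]] <-
        matrix(rnorm(widths[l] * widths[l + 1L], 0, sqrt(2 / widths[l])),
               widths[l], widths[l + 1L])
    }
    d <- widths[cfg$n_layers + 1L]
    params[["Wfc"]] <- matrix(rnorm(cfg$n_classes * d, 0, sqrt(1 / d)),
                              cfg$n_classes, d)
    params[["bfc"]] <- numeric(cfg$n_classes)
  })
  params
}

# Forward pass for one image; x = selected feature values (one per node),
# optionally augmented with a one-hot node-identity encoding.
glnp_forward_one <- function(params, graph, x, n_layers, node_identity = TRUE) {
  H <- matrix(x, ncol = 1L)
  if (node_identity) H <- cbind(H, diag(length(x)))
  Hs <- vector("list", n_layers + 1L)
  Hs[[1L]] <- H
  for (l in seq_len(n_layers)) {
    Z <- graph$prop %*% Hs[[l]] %*% params[[paste0("W", l)]]
    Hs[[l + 1L]] <- pmax(Z, 0)
  }
  HL <- Hs[[n_layers + 1L]]
  amax <- max.col(t(HL), ties.method = "first")  # arg-max node per column
  z <- HL[cbind(amax, seq_len(ncol(HL)))]
  logits <- as.vector(params$Wfc %*% z) + as.vector(params$bfc)
  p <- as.vector(softmax_rows(matrix(logits, 1)))
  list(Hs = Hs, amax = amax, z = z, p = p)
}

glnp_backward_one <- function(params, graph, fwd, label1, n_layers) {
  dlogit <- fwd$p
  dlogit[label1] <- dlogit[label1] - 1
  grads <- list()
  grads$Wfc <- outer(dlogit, fwd$z)
  grads$bfc <- dlogit
  dz <- as.vector(t(params$Wfc) %*% dlogit)
  HL <- fwd$Hs[[n_layers + 1L]]
  dH <- matrix(0, nrow(HL), ncol(HL))
  dH[cbind(fwd$amax, seq_len(ncol(HL)))] <- dz
  for (l in rev(seq_len(n_layers))) {
    Zmask <- fwd$Hs[[l + 1L]] > 0
    dZ <- dH * Zmask
    PH <- graph$prop %*% fwd$Hs[[l]]
    grads[[paste0("W", l)]] <- crossprod(PH, dZ)
    dH <- crossprod(graph$prop, dZ %*% t(params[[paste0("W", l)]]))
  }
  grads
}

#' Train the graph-convolutional classifier
#'
#' Each image's selected feature values form the one-dimensional node
#' signals `H(0)` on the fixed feature graph; `n_layers` normalized graph
#' convolutions with ReLU, a global max pool and a softmax head produce
#' class probabilities.  Cross-entropy is minimized with Adam (initial
#' learning rate 0.001, x0.1 decay every 25 epochs).
#'
#' @param features Numeric matrix of *selected* feature columns (rows =
#'   images).
#' @param labels Integer class labels `0 .. n_classes-1` (one per row).
#' @param graph A `feature_graph` whose nodes correspond to the feature
#'   columns.
#' @param cfg A [glnp_config()].
#' @param train_cfg List: `epochs` (default 60), `batch_size` (4),
#'   `lr` (1e-3), `decay_every` (25), `decay_factor` (0.1).
#' @param seed Shuffling seed.
#'
#' @return An object of class `glnp_model` with `params`, `graph`, `cfg`,
#'   `loss_history` and column scaling.
#' @export
train_classifier <- function(features, labels, graph, cfg,
                             train_cfg = list(), seed = 1L) {
  features <- as.matrix(features)
  assert_that(ncol(features) == graph$n_nodes,
              "feature columns must match graph nodes")
  assert_that(nrow(features) == length(labels), "features/labels mismatch")
  assert_that(max(labels) < cfg$n_classes && min(labels) >= 0,
              "labels outside 0..n_classes-1")
  tc <- utils::modifyList(list(epochs = 60L, batch_size = 4L, lr = 1e-3,
                               decay_every = 25L, decay_factor = 0.1),
                          train_cfg)
  # standardize node signals once (training-set statistics)
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")
  params <- glnp_init_params(cfg, graph$n_nodes)
  state <- adam_init(params)
  n <- nrow(Z)
  losses <- numeric(tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_schedule(epoch, tc$lr, tc$decay_factor, tc$decay_every)
    ord <- withr::with_seed(derive_seed(seed, epoch), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      grads <- NULL
      bl <- 0
      for (i in idx) {
        fwd <- glnp_forward_one(params, graph, Z[i, ], cfg$n_layers,
                                cfg$node_identity)
        bl <- bl - log(max(fwd$p[labels[i] + 1L], 1e-12))
        g <- glnp_backward_one(params, graph, fwd, labels[i] + 1L,
                               cfg$n_layers)
        grads <- if (is.null(grads)) g else
          Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(idx))
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bl
    }
    losses[epoch] <- ep_loss / n
  }
  structure(list(params = params, graph = graph, cfg = cfg,
                 loss_history = losses, center = mu, scale = sdv),
            class = "glnp_model")
}

#' @export
print.glnp_model <- function(x, ...) {
  cat(sprintf("<glnp_model> %d gcn layers on %d nodes, %d classes; final loss %.4f\n",
              x$cfg$n_layers, x$graph$n_nodes, x$cfg$n_classes,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict disease classes with a trained GLNP model
#'
#' @param object A `glnp_model`.
#' @param features Matrix of selected feature columns (rows = images).
#' @param ... Unused.
#'
#' @return A tibble with `predicted` (0-based label), `confidence`, and a
#'   `probs` list-column of full probability vectors.
#' @export
predict.glnp_model <- function(object, features, ...) {
  features <- as.matrix(features)
  assert_that(ncol(features) == object$graph$n_nodes,
              "feature columns must match graph nodes")
  Z <- sweep(sweep(features, 2L, object$center), 2L, object$scale, "/")
  rows <- lapply(seq_len(nrow(Z)), function(i) {
    fwd <- glnp_forward_one(object$params, object$graph, Z[i, ],
                            object$cfg$n_layers, object$cfg$node_identity)
    tibble::tibble(predicted = which.max(fwd$p) - 1L,
                   confidence = max(fwd$p), probs = list(fwd$p))
  })
  dplyr::bind_rows(rows)
}
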