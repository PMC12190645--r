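test_that("cosine similarity matches its analytic cases and rejects zero vectors", {
  v <- c(0.3, -0.2, 0.9)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), v[1:2]),
               class = "cropdx_undefined_similarity_error")
})

test_that("graph construction thresholds pairwise similarities exactly", {
  withr::with_seed(3, P <- matrix(rnorm(40), 8, 5))
  cfg <- glnp_config(n_classes = 3, edge_threshold = 0.5)
  g <- build_graph(P, cfg)
  for (i in 1:4) for (j in (i + 1):5) {
    s <- sum(P[, i] * P[, j]) / sqrt(sum(P[, i]^2) * sum(P[, j]^2))
    expect_equal(g$adjacency[i, j], if (s >= 0.5) s else 0)
  }
  expect_equal(diag(g$adjacency), rep(0, 5))
  expect_true(all(g$degree > 0))
  # threshold 1 on generic profiles: edgeless, self-loops only
  g1 <- build_graph(P, glnp_config(n_classes = 3, edge_threshold = 1))
  expect_equal(g1$adjacency, matrix(0, 5, 5))
  expect_equal(g1$prop, diag(5))
  # duplicated profiles give a unit edge
  g2 <- build_graph(cbind(P[, 1], P[, 1]), cfg)
  expect_equal(g2$adjacency[1, 2], 1)
  expect_equal(nrow(graph_edge_list(g2)), 1)
})

test_that("a gcn layer equals the dense normalized-propagation oracle", {
  one <- build_graph(matrix(c(1, 2, 1.9, 4.1), 2, 2), glnp_config(n_classes = 2))
  # single positive node value with identity weights propagates unchanged
  single <- list(prop = matrix(1, 1, 1), n_nodes = 1L)
  class(single) <- "feature_graph"
  expect_equal(gcn_layer(matrix(2.5), single, diag(1)), matrix(2.5))
  withr::with_seed(9, {
    P <- matrix(rnorm(60), 10, 6)
    g <- build_graph(P, glnp_config(n_classes = 2, edge_threshold = 0.2))
    H <- matrix(rnorm(18), 6, 3)
    W <- matrix(rnorm(12), 3, 4)
  })
  out <- gcn_layer(H, g, W)
  # explicit-loop oracle
  m <- 6
  Ap <- g$adjacency + diag(m)
  D <- rowSums(Ap)
  oracle <- matrix(0, m, 4)
  for (i in 1:m) for (k in 1:4) {
    acc <- 0
    for (j in 1:m) for (l in 1:3) {
      acc <- acc + Ap[i, j] / sqrt(D[i] * D[j]) * H[j, l] * W[l, k]
    }
    oracle[i, k] <- max(acc, 0)
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("the normalized propagation operator is non-expanding and permutation-equivariant", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      P <- matrix(rnorm(7 * 24), 24, 7)
      g <- build_graph(P, glnp_config(n_classes = 2, edge_threshold = 0.3))
      expect_lte(max(abs(eigen(g$prop, only.values = TRUE)$values)), 1 + 1e-10)
      H <- matrix(rnorm(7 * 3), 7, 3)
      W <- matrix(rnorm(6), 3, 2)
      perm <- sample(7)
      gp <- g
      gp$prop <- g$prop[perm, perm]
      out <- gcn_layer(H, g, W)
      out_p <- gcn_layer(H[perm, ], gp, W)
      expect_equal(out_p, out[perm, ], tolerance = 1e-12)
      expect_equal(graph_pool(out_p), graph_pool(out))
    }
  })
})

test_that("graph pooling is the columnwise maximum", {
  withr::with_seed(2, H <- matrix(rnorm(20), 5, 4))
  z <- graph_pool(H)
  for (k in 1:4) expect_equal(z[k], max(H[, k]))
  expect_equal(graph_pool(H[2, , drop = FALSE]), H[2, ])
  dominant <- rbind(H, apply(H, 2, max) + 1)
  expect_equal(graph_pool(dominant), dominant[6, ])
})

test_that("the softmax head is uniform at zero, overflow-safe and oracle-exact", {
  expect_equal(classify(rep(0, 4), matrix(0, 3, 4), rep(0, 3)), rep(1 / 3, 3))
  big <- classify(c(1), matrix(c(1000, 0), 2, 1), c(0, 0))
  expect_equal(big, c(1, 0), tolerance = 1e-12)
  withr::with_seed(6, {
    z <- rnorm(5); W <- matrix(rnorm(20), 4, 5); b <- rnorm(4)
  })
  expect_equal(classify(z, W, b), oracle_softmax(as.vector(W %*% z) + b),
               tolerance = 1e-12)
  expect_error(classify(c(Inf, 1), matrix(1, 2, 2), c(0, 0)),
               class = "cropdx_numeric_error")
})

test_that("with an edgeless graph the network reduces to per-feature transforms plus pooling", {
  withr::with_seed(4, X <- matrix(runif(60, 0.2, 1), 12, 5))
  cfg <- glnp_config(n_layers = 2, widths = c(4L, 6L), n_classes = 2,
                     edge_threshold = 1, seed = 8)
  g <- build_graph(X, cfg)
  params <- cropdx:::glnp_init_params(cfg, 5)
  x <- X[1, ]
  fwd <- cropdx:::glnp_forward_one(params, g, x, 2, cfg$node_identity)
  # reduced computation: each node transformed independently
  H0 <- cbind(matrix(x, ncol = 1), diag(5))
  H1 <- pmax(H0 %*% params$W1, 0)
  H2 <- pmax(H1 %*% params$W2, 0)
  expect_equal(fwd$z, apply(H2, 2, max), tolerance = 1e-12)
})

test_that("training separates class-coherent features and shuffled labels stay at chance", {
  withr::with_seed(7, {
    labels <- rep(0:2, length.out = 120)
    base <- runif(10, 0.5, 1.5)
    shifts <- c(0.6, 1.0, 1.6)
    X <- t(sapply(seq_along(labels),
                  function(i) shifts[labels[i] + 1] * base + rnorm(10, 0, 0.15)))
  })
  cfg <- glnp_config(n_classes = 3, seed = 5)
  g <- build_graph(scale(X, scale = FALSE), cfg)
  model <- train_classifier(X, labels, g, cfg, list(epochs = 40), seed = 6)
  pred <- predict(model, X)
  expect_gte(mean(pred$predicted == labels), 0.95)
  expect_true(all(abs(vapply(pred$probs, sum, numeric(1)) - 1) < 1e-12))
  model_b <- train_classifier(X, labels, g, cfg, list(epochs = 40), seed = 6)
  expect_equal(model$loss_history, model_b$loss_history, tolerance = 1e-12)
  # permutation null: shuffled labels give chance-level held-out accuracy
  withr::with_seed(8, yshuf <- sample(labels))
  tr <- 1:90; te <- 91:120
  mnull <- train_classifier(X[tr, ], yshuf[tr], g, cfg,
                            list(epochs = 25), seed = 9)
  pnull <- predict(mnull, X[te, ])
  expect_lt(mean(pnull$predicted == yshuf[te]), 0.66)
})
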