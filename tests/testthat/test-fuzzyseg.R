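test_that("Gaussian membership has its analytic values and symmetry", {
  p <- membership_params(100, 15)
  expect_equal(gaussian_membership(100, p), 1)
  expect_equal(gaussian_membership(115, p), exp(-1 / 2))
  expect_equal(gaussian_membership(85, p), exp(-1 / 2))
  for (d in c(3, 7.5, 40)) {
    expect_equal(gaussian_membership(100 + d, p), gaussian_membership(100 - d, p))
  }
  expect_error(membership_params(100, 0), class = "cropdx_validation_error")
  expect_error(membership_params(300, 5), class = "cropdx_validation_error")
})

test_that("Mamdani min-implication is a commutative, idempotent, monotone t-norm", {
  expect_equal(mamdani_implication(0.7, 0.4), 0.4)
  expect_equal(mamdani_implication(0.55, 0.55), 0.55)
  expect_equal(mamdani_implication(0.8, 0), 0)
  withr::with_seed(1, {
    a <- runif(20); b <- runif(20)
    expect_equal(mamdani_implication(a, b), mamdani_implication(b, a))
    expect_true(all(mamdani_implication(pmin(a + 0.1, 1), b) >=
                    mamdani_implication(a, b)))
  })
  expect_error(mamdani_implication(1.2, 0.5), class = "cropdx_validation_error")
})

test_that("rule application equals a per-pixel scalar evaluation", {
  withr::with_seed(2, {
    p <- matrix(runif(64), 8, 8)
    q <- matrix(runif(64), 8, 8)
    r <- matrix(runif(64), 8, 8)
    s <- matrix(runif(64), 8, 8)
  })
  cur <- list(A = p, B = r)
  prev <- list(A = q, B = s)
  rules <- data.frame(a = c("A", "B"), b = c("A", "B"), c = c("C", "C"))
  fused <- apply_fuzzy_rules(cur, prev, rules)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    oracle[i, j] <- max(min(p[i, j], q[i, j]), min(r[i, j], s[i, j]))
  }
  expect_equal(fused$C, oracle)
  ones <- matrix(1, 8, 8)
  expect_equal(apply_fuzzy_rules(list(A = ones), list(A = ones))$A, ones)
  zero <- matrix(0, 8, 8)
  expect_equal(apply_fuzzy_rules(list(A = zero), list(A = ones))$A, zero)
  expect_error(apply_fuzzy_rules(cur, prev, data.frame(a = "Z", b = "A", c = "C")),
               class = "cropdx_config_error")
})

test_that("centroid defuzzification matches direct weighted means and stays in the support", {
  expect_equal(centroid_defuzzify(rep(1, 256)), 127.5)
  point <- rep(0, 256); point[201] <- 1  # intensity 200
  expect_equal(centroid_defuzzify(point), 200)
  tri <- rep(0, 256)
  tri[11:21] <- c(1:4, 5, 4:1, 0.5, 0.25)  # peaked near 14
  expect_equal(centroid_defuzzify(tri), sum((10:20) * tri[11:21]) / sum(tri))
  expect_gte(centroid_defuzzify(tri), 10)
  expect_lte(centroid_defuzzify(tri), 20)
  expect_error(centroid_defuzzify(rep(0, 256)),
               class = "cropdx_undefined_centroid_error")
})

test_that("network construction is deterministic with a parameter count matching an arithmetic tally", {
  cfg <- unetpp_config(depth = 3, filters = c(8L, 16L, 32L), in_channels = 1,
                       n_classes = 5, seed = 21)
  m1 <- build_unetpp(cfg)
  m2 <- build_unetpp(cfg)
  expect_identical(m1$params, m2$params)
  # independent tally: per node, two 3x3 convs (+bias) and two BN (gamma,
  # beta); head is 1x1 conv f1 -> K
  f <- c(8, 16, 32)
  tally <- 0
  node_cin <- function(i, j) if (j == 0) (if (i == 0) 1 else f[i]) else
    j * f[i + 1] + f[i + 2]
  for (j in 0:2) for (i in 0:(2 - j)) {
    cin <- node_cin(i, j); cout <- f[i + 1]
    tally <- tally + 9 * cin * cout + cout + 9 * cout * cout + cout +
      4 * cout
  }
  tally <- tally + 8 * 5 + 5
  expect_equal(unetpp_param_count(m1), tally)
  expect_error(unetpp_config(depth = 3, filters = c(8L, 16L)),
               class = "cropdx_validation_error")
})

test_that("a depth-1 configuration degenerates to a plain conv encoder-decoder", {
  cfg <- unetpp_config(depth = 1, filters = 4L, in_channels = 1,
                       n_classes = 3, seed = 2)
  model <- build_unetpp(cfg)
  expect_setequal(grep("^n", names(model$params), value = TRUE),
                  paste0("n0_0_", c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2")))
  img <- matrix(runif(64), 8, 8)
  sm <- segment(img, model)
  expect_equal(dim(sm$labels), c(8L, 8L))
})

test_that("segmentation is deterministic with memberships in range", {
  spec <- tiny_phantom_spec()
  item <- generate_leaf_image(spec, 1, seed = 4)
  cfg <- unetpp_config(depth = 3, filters = c(4L, 8L, 16L), in_channels = 1,
                       n_classes = 5, seed = 13)
  model <- build_unetpp(cfg)
  mp <- fit_membership_params(list(item$image), list(item$mask), 5)
  s1 <- segment(item$image, model, mp)
  s2 <- segment(item$image, model, mp)
  expect_identical(s1, s2)
  expect_true(all(s1$memberships >= 0 & s1$memberships <= 1))
  expect_true(all(s1$labels >= 0 & s1$labels <= 4))
  expect_true(all(s1$coa >= 0 & s1$coa <= 255))
})

test_that("training reduces the loss and a trained model segments pure-colour leaves", {
  spec <- tiny_phantom_spec()
  ds <- generate_dataset(spec, n_per_class = 4, seed = 17)
  cfg <- unetpp_config(depth = 2, filters = c(6L, 12L), in_channels = 1,
                       n_classes = 5, seed = 19)
  model <- train_segmenter(ds, cfg, list(epochs = 6, batch_size = 4), seed = 23)
  expect_length(model$loss_history, 6)
  expect_lt(model$loss_history[6], model$loss_history[1])
  model_b <- train_segmenter(ds, cfg, list(epochs = 6, batch_size = 4), seed = 23)
  expect_equal(model$loss_history, model_b$loss_history, tolerance = 1e-12)
  mp <- fit_membership_params(ds$images, ds$masks, 5)
  item <- generate_leaf_image(spec, 2, seed = 99)
  sm <- segment(item$image, model, mp)
  leaf_px <- item$mask >= 1
  expect_gt(mean((sm$labels == item$mask)[leaf_px]), 0.97)
  expect_error(train_segmenter(list(images = list(), masks = list()), cfg),
               class = "cropdx_validation_error")
})

test_that("segmentation metrics match a pixel-loop oracle and pin the extremes", {
  truth <- matrix(c(0L, 1L)[1 + (outer(1:8, 1:8, `+`) %% 2)], 8, 8)
  perfect <- segmentation_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mean_iou, 1)
  expect_equal(perfect$fuzzy_overlap, 1)
  worst <- segmentation_metrics(1L - truth, truth)
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$mean_iou, 0)
  withr::with_seed(31, {
    for (rep in 1:3) {
      pred <- matrix(sample(0:2, 64, TRUE), 8, 8)
      tr <- matrix(sample(0:2, 64, TRUE), 8, 8)
      got <- segmentation_metrics(pred, tr, n_classes = 3)
      want <- oracle_seg_metrics(pred, tr)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$mean_iou, want$mean_iou)
      expect_equal(got$fuzzy_overlap, want$fuzzy_overlap)
    }
  })
  expect_error(segmentation_metrics(truth, truth + 5L, n_classes = 2),
               class = "cropdx_validation_error")
})
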