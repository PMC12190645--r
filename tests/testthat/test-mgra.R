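test_that("convolutional features match a quadruple-loop oracle", {
  withr::with_seed(5, {
    I <- matrix(runif(36), 6, 6)
    w <- matrix(rnorm(9), 3, 3)
    b <- matrix(rnorm(9, 0, 0.1), 3, 3)
  })
  bank <- list(weights = array(w, c(3, 3, 1)), biases = array(b, c(3, 3, 1)))
  expect_equal(conv_features(I, bank), oracle_conv_feature(I, w, b),
               tolerance = 1e-12)
  # delta kernel on a constant image returns the constant
  delta <- array(0, c(3, 3, 1)); delta[2, 2, 1] <- 1
  bank_d <- list(weights = delta, biases = array(0, c(3, 3, 1)))
  expect_equal(conv_features(matrix(0.4, 10, 10), bank_d), 0.4)
  # zero kernel with a bias map returns the summed bias
  bank_b <- list(weights = array(0, c(3, 3, 1)),
                 biases = array(1 / 9, c(3, 3, 1)))
  expect_equal(conv_features(matrix(0.8, 10, 10), bank_b), 1)
  expect_error(conv_features(matrix(1, 2, 2), bank), class = "cropdx_validation_error")
})

test_that("gorilla updates follow the movement equation with clipping", {
  expect_equal(gorilla_update(c(0.2, 0.9), c(0.6, 0.3), stoch = 0), c(0.6, 0.3))
  expect_equal(gorilla_update(c(0.4, 0.4), c(0.4, 0.4), stoch = 0.7), c(0.4, 0.4))
  expect_equal(gorilla_update(0.2, 0.8, stoch = 1), 1)  # raw 1.4 clips
  withr::with_seed(3, {
    out <- gorilla_update(runif(10), runif(10))
    expect_true(all(out >= 0 & out <= 1))
  })
  expect_error(gorilla_update(c(0.1, 0.2), 0.5), class = "cropdx_validation_error")
})

test_that("attachment strength is the normalized mean absolute deviation", {
  expect_equal(attachment_strength(rep(0.3, 6)), 0)
  expect_equal(attachment_strength(c(0, 1)), 1)
  withr::with_seed(7, x <- runif(10))
  expect_equal(attachment_strength(x),
               sum(abs(x - mean(x))) / length(x) / 0.5)
  expect_error(attachment_strength(numeric(0)), class = "cropdx_validation_error")
})

test_that("remora updates interpolate between host and best", {
  h <- c(0.2, 0.8, 0.5)
  expect_equal(remora_update(h, h), h)
  expect_equal(remora_update(rep(0.4, 4), c(0, 1, 0, 1)), rep(0.4, 4))  # f = 0
  # f = 1 host reaches best exactly
  expect_equal(remora_update(c(0, 1), c(0.3, 0.3)), c(0.3, 0.3))
  withr::with_seed(11, {
    host <- runif(8); best <- runif(8)
    out <- remora_update(host, best)
    expect_true(all(out >= pmin(host, best) - 1e-12 &
                    out <= pmax(host, best) + 1e-12))
  })
})

test_that("redundancy is mean absolute pairwise correlation with documented edge cases", {
  withr::with_seed(13, X <- matrix(rnorm(600), 200, 3))
  expect_equal(redundancy(X[, 1, drop = FALSE]), 0)
  expect_equal(redundancy(cbind(X[, 1], X[, 1])), 1)
  expect_lt(redundancy(X), 0.2)
  cm <- abs(cor(X))
  expect_equal(redundancy(X), mean(cm[upper.tri(cm)]))
  # zero-variance column counts as maximally redundant
  expect_equal(redundancy(cbind(X[, 1], rep(2, 200))), 1)
})

test_that("fitness composes accuracy and redundancy as J = alpha*acc - beta*red", {
  pl <- planted_feature_problem(120, 6, 2, effect = 8, seed = 3)
  bundle <- make_eval_bundle(pl$features, pl$labels, seed = 5)
  cfg10 <- mgra_config(alpha = 1, beta = 0)
  expect_equal(fitness(as.integer(pl$informative), bundle, cfg10), 1.0)
  dup <- cbind(pl$features[, 1], pl$features[, 1])
  bundle_dup <- make_eval_bundle(dup, pl$labels, seed = 5)
  cfg01 <- mgra_config(alpha = 0, beta = 1)
  expect_equal(fitness(c(1L, 2L), bundle_dup, cfg01), -1.0)
  cfg_mix <- mgra_config(alpha = 1, beta = 0.5)
  sel <- c(1L, 2L, 4L)
  acc <- cropdx:::nearest_centroid_accuracy(pl$features[, sel], pl$labels,
                                            bundle$train_idx, bundle$test_idx)
  expect_equal(fitness(sel, bundle, cfg_mix),
               acc - 0.5 * redundancy(pl$features[, sel]))
  expect_equal(fitness(rep(0.1, 6), bundle, cfg_mix), -Inf)
})

test_that("select_features is elitist with a complete history and in-range positions", {
  pl <- planted_feature_problem(90, 8, 2, seed = 9)
  cfg <- mgra_config(population = 8, generations = 12, seed = 4)
  res <- select_features(pl$features, pl$labels, cfg)
  expect_length(res$history, 13)
  expect_true(all(diff(res$history) >= 0))
  expect_true(all(res$best_coords >= 0 & res$best_coords <= 1))
  expect_equal(res$selected, which(res$best_coords > 0.5))
  res0 <- select_features(pl$features, pl$labels,
                          mgra_config(population = 8, generations = 0, seed = 4))
  expect_length(res0$history, 1)
  expect_equal(res0$best_fitness, res0$history[1])
})

test_that("selection ratios reproduce the worked-example arithmetic", {
  expect_equal(selection_ratio(1024, 256), 25)
  expect_equal(selection_ratio(1024, 248), 24.2)
  expect_equal(selection_ratio(1024, 262), 25.6)
  expect_equal(selection_ratio(1024, 0), 0)
  expect_error(selection_ratio(10, 11), class = "cropdx_validation_error")
})
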