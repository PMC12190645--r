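test_that("a no-lesion noiseless spec renders only background and leaf", {
  spec <- phantom_spec(image_size = 48, n_classes = 2, noise_sigma = 0,
                       lesion_count_range = c(0L, 0L),
                       lesion_radius_range = c(4, 6))
  out <- generate_leaf_image(spec, class_id = 0, seed = 3)
  expect_setequal(unique(as.vector(out$mask)), c(0L, 1L))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("rendering is a pure function of (spec, class, seed)", {
  spec <- tiny_phantom_spec(noise = 0.05)
  a <- generate_leaf_image(spec, 1, seed = 11)
  b <- generate_leaf_image(spec, 1, seed = 11)
  expect_identical(a, b)
  c <- generate_leaf_image(spec, 1, seed = 12)
  expect_false(identical(a$image, c$image))
})

test_that("mask labels and lesion containment follow the geometry contract", {
  spec <- tiny_phantom_spec()
  for (cl in 0:2) {
    out <- generate_leaf_image(spec, cl, seed = 20 + cl)
    labs <- unique(as.vector(out$mask))
    expect_true(all(labs %in% c(0L, 1L, cl + 2L)))
    # lesions lie entirely within the leaf ellipse, and the labelled
    # foreground matches the rendered geometry exactly
    lesion <- out$mask == cl + 2L
    expect_gt(sum(lesion), 0)
    expect_true(all(out$leaf[lesion]))
    expect_true(all((out$mask >= 1L) == out$leaf))
  }
})

test_that("measured noise matches the requested sigma on interior pixels", {
  spec <- phantom_spec(image_size = 128, n_classes = 3, noise_sigma = 0.05,
                       lesion_count_range = c(2L, 2L),
                       lesion_radius_range = c(8, 12))
  spec0 <- spec
  spec0$noise_sigma <- 0
  noisy <- generate_leaf_image(spec, 0, seed = 5)
  clean <- generate_leaf_image(spec0, 0, seed = 5)
  resid <- (noisy$image - clean$image)
  # interior = away from clipping: leaf pixels at mid intensities
  sel <- clean$mask == 1L
  res_sd <- sd(resid[, , 2][sel])
  expect_lt(abs(res_sd - 0.05), 0.005)
})

test_that("invalid phantom requests are rejected", {
  spec <- tiny_phantom_spec()
  expect_error(generate_leaf_image(spec, 3, seed = 1), class = "cropdx_domain_error")
  expect_error(phantom_spec(lesion_radius_range = c(5, 2)),
               class = "cropdx_validation_error")
  expect_error(phantom_spec(image_size = 16), class = "cropdx_validation_error")
  expect_error(generate_dataset(spec, 0), class = "cropdx_validation_error")
})

test_that("generate_dataset is balanced, reproducible and duplicate-free", {
  spec <- tiny_phantom_spec(noise = 0.02)
  ds <- generate_dataset(spec, n_per_class = 4, seed = 7)
  expect_equal(nrow(ds$manifest), 12)
  expect_true(all(table(ds$manifest$label) == 4))
  ds2 <- generate_dataset(spec, n_per_class = 4, seed = 7)
  expect_identical(ds$images, ds2$images)
  sums <- vapply(ds$images, sum, numeric(1))
  expect_equal(length(unique(sums)), 12)  # no duplicate renders
})

test_that("add_noise obeys its statistical contract", {
  flat <- matrix(0.5, 256, 256)
  expect_identical(add_noise(flat, 0), flat)
  noisy <- add_noise(flat, 0.1, seed = 2)
  expect_lt(abs(sd(noisy - flat) - 0.1), 0.005)
  dark <- matrix(0, 64, 64)
  clipped <- add_noise(dark, 0.1, seed = 3)
  expect_gt(mean(clipped), 0)  # one-sided clipping bias
  expect_error(add_noise(flat, -0.1), class = "cropdx_validation_error")
})

test_that("well-separated noiseless classes are recoverable by mean lesion colour", {
  spec <- tiny_phantom_spec()
  ds <- generate_dataset(spec, n_per_class = 5, seed = 9)
  mean_col <- t(vapply(seq_along(ds$images), function(i) {
    les <- ds$masks[[i]] >= 2
    vapply(1:3, function(ch) mean(ds$images[[i]][, , ch][les]), numeric(1))
  }, numeric(3)))
  cents <- do.call(rbind, lapply(0:2, function(k)
    colMeans(mean_col[ds$manifest$label == k, , drop = FALSE])))
  pred <- apply(mean_col, 1, function(v)
    which.min(colSums((t(cents) - v)^2)) - 1L)
  expect_equal(pred, ds$manifest$label)
})
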