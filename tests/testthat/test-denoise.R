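test_that("edge_stopping matches its analytic fixed points and is monotone", {
  expect_equal(edge_stopping(0, 30), 1)
  expect_equal(edge_stopping(1 / 30, 30), 0.5)
  expect_equal(edge_stopping(3 / 30, 30), 0.1)
  g <- seq(0, 2, by = 0.05)
  expect_true(all(diff(edge_stopping(g, 5)) < 0))
  expect_error(edge_stopping(1, -1), class = "cropdx_validation_error")
})

test_that("local variance map agrees with a brute-force windowed oracle", {
  checker <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  expect_equal(local_variance_map(checker, 3), oracle_local_variance(checker, 3))
  spot <- matrix(0, 7, 7); spot[4, 4] <- 1
  vm <- local_variance_map(spot, 3)
  expect_equal(vm, oracle_local_variance(spot, 3))
  expect_equal(vm[1, 1], 0)
  expect_gt(vm[4, 4], vm[1, 1])
  expect_equal(local_variance_map(matrix(0.3, 5, 5), 3), matrix(0, 5, 5))
  expect_error(local_variance_map(checker, 4), class = "cropdx_validation_error")
})

test_that("the conductance map is flat-maximal, bounded by the edge term and edge-selective", {
  cfg <- diffusion_config()
  flat <- matrix(0.5, 16, 16) * 255
  expect_equal(diffusion_coefficient(flat, cfg), matrix(1, 16, 16))
  step <- step_phantom(32, 0.1, 0.9) * 255
  noisy <- add_noise(step_phantom(32, 0.1, 0.9), 0.05, seed = 4) * 255
  cmap <- diffusion_coefficient(noisy, cfg)
  # never exceeds the edge-stopping term alone (variance modulation <= 1)
  n <- nrow(noisy); m <- ncol(noisy)
  Ip <- cropdx:::pad_replicate(noisy, 1)
  gy <- (Ip[3:(n + 2), 2:(m + 1)] - Ip[1:n, 2:(m + 1)]) / 2
  gx <- (Ip[2:(n + 1), 3:(m + 2)] - Ip[2:(n + 1), 1:m]) / 2
  f_alone <- 1 / (1 + (sqrt(gx^2 + gy^2) / cfg$k)^2)
  expect_true(all(cmap <= f_alone + 1e-12))
  # conductance on the edge band is below the off-edge average
  edge_band <- cmap[, 16:17]
  off_edge <- cmap[, c(2:8, 25:31)]
  expect_lt(mean(edge_band), mean(off_edge))
})

test_that("diffusion steps fix constants and reduce to linear heat flow at c = 1", {
  cfg <- diffusion_config(lambda = 0.2, dt = 0.15)
  const <- matrix(0.4, 8, 8)
  st <- diffuse_step(list(image = const, iteration = 0L, last_delta = Inf), cfg)
  expect_equal(st$image, const)
  expect_equal(st$last_delta, 0)
  withr::with_seed(5, {
    for (rep in 1:5) {
      I <- matrix(runif(64), 8, 8)
      ones <- matrix(1, 8, 8)
      st <- diffuse_step(list(image = I, iteration = 0L, last_delta = Inf),
                         cfg, conductance = ones)
      expect_equal(st$image, oracle_heat_step(I, cfg$lambda * cfg$dt),
                   tolerance = 1e-12)
    }
  })
})

test_that("each diffusion step changes the mean by less than the stencil bound", {
  cfg <- diffusion_config()
  noisy <- add_noise(step_phantom(32), 0.1, seed = 8) * 255
  st <- diffuse_step(list(image = noisy, iteration = 0L, last_delta = Inf), cfg)
  lap_max <- max(abs(cropdx:::laplacian3(noisy)))
  expect_lt(abs(mean(st$image) - mean(noisy)), cfg$lambda * cfg$dt * lap_max)
  expect_true(is.finite(st$last_delta))
})

test_that("denoise terminates, respects tol = Inf, and reduces noise", {
  img <- add_noise(matrix(0.5, 48, 48), 0.1, seed = 2)
  one <- denoise(img, diffusion_config(tol = Inf))
  expect_equal(one$iterations_run, 1L)
  out <- denoise(img, diffusion_config())
  expect_lte(out$iterations_run, 20L)
  expect_lt(sd(out$image - 0.5), sd(img - 0.5))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("colour denoising shares conductance and stays in range", {
  spec <- tiny_phantom_spec(noise = 0.05, size = 32)
  img <- generate_leaf_image(spec, 0, seed = 2)$image
  out <- denoise(img, diffusion_config(n_iter = 5))
  expect_equal(dim(out$image), dim(img))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("noise_level is calibrated, scale-equivariant and zero on constants", {
  expect_equal(noise_level(matrix(0.7, 32, 32)), 0)
  img <- add_noise(matrix(0.5, 128, 128), 0.1, seed = 6)
  est <- noise_level(img)
  expect_lt(abs(est - 0.1) / 0.1, 0.15)
  expect_equal(noise_level(img * 0.5), 0.5 * est, tolerance = 1e-12)
  expect_error(noise_level(matrix(0, 8, 8)), class = "cropdx_validation_error")
})

test_that("edge preservation index is 1 on identity, errors on constants, and favours diffusion over blur", {
  img <- step_phantom(64)
  expect_equal(edge_preservation_index(img, img), 1)
  expect_error(edge_preservation_index(img, matrix(0.5, 64, 64)),
               class = "cropdx_undefined_index_error")
  clean <- step_phantom(64, 0.1, 0.9)
  noisy <- add_noise(clean, 0.1, seed = 3)
  dn <- denoise(noisy, diffusion_config())$image
  # equal-strength uniform blur comparator (iterated box = near-Gaussian)
  gauss <- cropdx:::box_mean(cropdx:::box_mean(noisy, 3), 3)
  expect_gt(edge_preservation_index(clean, dn),
            edge_preservation_index(clean, gauss))
})

test_that("denoise_report mirrors the per-image summary columns", {
  imgs <- list(add_noise(step_phantom(32), 0.08, seed = 1),
               add_noise(step_phantom(32), 0.08, seed = 2))
  rep <- denoise_report(imgs, diffusion_config(n_iter = 5))
  expect_named(rep, c("image_id", "noise_level_before", "noise_level_after",
                      "edge_preservation_index", "iterations_run", "denoised"))
  expect_equal(rep$image_id, c("Img01", "Img02"))
  expect_true(all(rep$noise_level_after < rep$noise_level_before))
})

test_that("a noiseless step edge survives diffusion almost untouched", {
  clean <- step_phantom(48, 0.1, 0.9)
  out <- denoise(clean, diffusion_config())$image
  expect_gte(edge_preservation_index(clean, out), 0.95)
})
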