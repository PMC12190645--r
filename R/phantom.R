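#' Specification of a synthetic leaf phantom
#'
#' A phantom is a leaf-shaped ellipse on a flat background carrying a number
#' of smooth lesion blobs whose colour identifies the disease class.  The
#' generator is fully parametric so every pipeline stage can be exercised
#' against exact ground truth: the returned mask agrees pixel-for-pixel with
#' the rendered geometry.
#'
#' Mask labels are `0` (background), `1` (healthy leaf tissue) and
#' `2 .. n_classes + 1` (lesion pixels of disease class `0 .. n_classes - 1`).
#'
#' @param image_size Integer vector of length 1 or 2, output size in pixels
#'   (rows, cols).  Default 256.
#' @param n_classes Number of disease classes (2--5).
#' @param lesion_count_range Integer interval, number of lesions per image.
#' @param lesion_radius_range Numeric interval, nominal lesion radius in
#'   pixels.
#' @param class_color_means List (length `n_classes`) of RGB triplets in
#'   `[0,1]`, the mean lesion colour per class.  `NULL` uses a built-in
#'   well-separated palette.
#' @param leaf_color RGB triplet of healthy tissue.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (intensity units, applied after rendering and clipped to `[0,1]`).
#' @param background_level Background intensity.
#' @param seed Default RNG seed used when an operation is not given one.
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(image_size = 64, n_classes = 3, noise_sigma = 0)
#' out <- generate_leaf_image(spec, class_id = 1, seed = 7)
#' table(out$mask)
phantom_spec <- function(image_size = c(256L, 256L),
                         n_classes = 3L,
                         lesion_count_range = c(2L, 5L),
                         lesion_radius_range = NULL,
                         class_color_means = NULL,
                         leaf_color = c(0.25, 0.55, 0.25),
                         noise_sigma = 0.05,
                         background_level = 0.08,
                         seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  assert_that(all(image_size >= 32L), "image_size must be at least 32x32")
  assert_that(n_classes >= 2L && n_classes <= 5L, "n_classes must be in 2..5")
  if (is.null(lesion_radius_range)) {
    lesion_radius_range <- round(c(0.05, 0.12) * min(image_size))
  }
  assert_that(length(lesion_count_range) == 2L &&
                lesion_count_range[1] <= lesion_count_range[2] &&
                lesion_count_range[1] >= 0,
              "invalid lesion_count_range")
  assert_that(length(lesion_radius_range) == 2L &&
                lesion_radius_range[1] <= lesion_radius_range[2] &&
                lesion_radius_range[1] > 0,
              "degenerate lesion_radius_range")
  if (is.null(class_color_means)) {
    class_color_means <- default_lesion_palette(n_classes)
  }
  assert_that(length(class_color_means) == n_classes,
              "class_color_means must have one RGB triplet per class")
  for (cc in class_color_means) {
    assert_that(length(cc) == 3L && all(cc >= 0) && all(cc <= 1),
                "class colour means must be RGB triplets in [0,1]")
  }
  assert_that(noise_sigma >= 0, "noise_sigma must be non-negative")
  assert_that(background_level >= 0 && background_level <= 1,
              "background_level must lie in [0,1]")
  structure(
    list(image_size = image_size, n_classes = as.integer(n_classes),
         lesion_count_range = as.integer(lesion_count_range),
         lesion_radius_range = as.numeric(lesion_radius_range),
         class_color_means = class_color_means,
         leaf_color = leaf_color, noise_sigma = noise_sigma,
         background_level = background_level, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Well separated in luminance so that colour alone identifies the class.
default_lesion_palette <- function(n_classes) {
  base <- list(
    c(0.95, 0.88, 0.35),  # bright chlorotic yellow
    c(0.55, 0.27, 0.10),  # mid brown necrosis
    c(0.16, 0.10, 0.08),  # dark necrotic spot
    c(0.95, 0.95, 0.95),  # powdery white
    c(0.75, 0.45, 0.55)   # rust pink
  )
  base[seq_len(n_classes)]
}

#' Render one leaf phantom with its ground-truth mask
#'
#' Draws a rotated ellipse of healthy tissue on a flat background, places
#' smooth random lesion blobs of the requested disease class strictly inside
#' the leaf, and finally adds clipped Gaussian pixel noise.  The render is a
#' pure function of `(spec, class_id, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param class_id Disease class of the image, `0 .. n_classes - 1`.
#' @param seed RNG seed; defaults to `spec$seed`.
#'
#' @return A list with elements `image` (`H x W x 3` array in `[0,1]`),
#'   `mask` (`H x W` integer matrix of segmentation labels), `label`
#'   (= `class_id`) and `leaf` (logical matrix of the leaf ellipse, for
#'   geometry checks).
#' @export
generate_leaf_image <- function(spec, class_id, seed = spec$seed) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  assert_that(length(class_id) == 1L && class_id >= 0 &&
                class_id < spec$n_classes,
              sprintf("class_id must be in 0..%d", spec$n_classes - 1L),
              class = "cropdx_domain_error")
  withr::with_seed(as.integer(seed), render_phantom(spec, as.integer(class_id)))
}

render_phantom <- function(spec, class_id) {
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  # leaf ellipse
  cy <- h / 2 + runif(1, -0.05, 0.05) * h
  cx <- w / 2 + runif(1, -0.05, 0.05) * w
  a <- runif(1, 0.30, 0.42) * h
  b <- runif(1, 0.24, 0.36) * w
  th <- runif(1, 0, pi)
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(th) * yy + sin(th) * xx
  v <- -sin(th) * yy + cos(th) * xx
  leaf <- (u / a)^2 + (v / b)^2 <= 1
  mask <- matrix(0L, h, w)
  mask[leaf] <- 1L

  cr <- spec$lesion_count_range
  n_lesion <- cr[1] + sample.int(cr[2] - cr[1] + 1L, 1L) - 1L
  for (k in seq_len(n_lesion)) {
    blob <- place_lesion(leaf, spec$lesion_radius_range, h, w)
    if (!is.null(blob)) mask[blob] <- class_id + 2L
  }

  img <- array(spec$background_level, c(h, w, 3))
  col_leaf <- spec$leaf_color
  col_les <- spec$class_color_means[[class_id + 1L]]
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask == 1L] <- col_leaf[ch]
    plane[mask == class_id + 2L] <- col_les[ch]
    img[, , ch] <- plane
  }
  if (spec$noise_sigma > 0) {
    img <- clip01(img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img)))
  }
  list(image = img, mask = mask, label = class_id, leaf = leaf)
}

# A smooth star-shaped blob: a disk whose radius is modulated by random
# low-order harmonics.  Retries (shrinking if necessary) until the blob lies
# entirely inside the leaf; returns a logical mask or NULL if the leaf is
# too small.
place_lesion <- function(leaf, radius_range, h, w) {
  inside <- which(leaf)
  if (length(inside) == 0L) return(NULL)
  r0 <- runif(1, radius_range[1], radius_range[2])
  for (attempt in 1:60) {
    if (attempt %% 15 == 0) r0 <- max(2, r0 * 0.7)
    pick <- inside[sample.int(length(inside), 1L)]
    cy <- (pick - 1L) %% h + 1L
    cx <- (pick - 1L) %/% h + 1L
    a1 <- runif(1, 0, 0.25); p1 <- runif(1, 0, 2 * pi)
    a2 <- runif(1, 0, 0.20); p2 <- runif(1, 0, 2 * pi)
    rr <- ceiling(r0 * 1.5)
    ys <- max(1L, cy - rr):min(h, cy + rr)
    xs <- max(1L, cx - rr):min(w, cx + rr)
    dy <- matrix(ys - cy, length(ys), length(xs))
    dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
    ang <- atan2(dx, dy)
    rad <- r0 * (1 + a1 * sin(2 * ang + p1) + a2 * sin(3 * ang + p2))
    blob_local <- sqrt(dy^2 + dx^2) <= rad
    # blob clipped by the image border does not count as contained
    clipped <- (cy - rr < 1) || (cy + rr > h) || (cx - rr < 1) || (cx + rr > w)
    blob <- matrix(FALSE, h, w)
    blob[ys, xs] <- blob_local
    if (!clipped && all(leaf[blob])) return(blob)
  }
  NULL
}

#' Generate a balanced phantom dataset
#'
#' Renders `n_per_class` phantoms for every disease class with per-item seeds
#' derived from the master seed by a counter scheme, so any subset of the
#' dataset is reproducible independently of generation order.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_class Images per class (>= 1).
#' @param seed Master seed; defaults to `spec$seed`.
#'
#' @return An object of class `phantom_dataset`: a list with `manifest`
#'   (tibble: `item`, `label`, `seed`), `images` and `masks` (lists), and the
#'   generating `spec`.
#' @export
generate_dataset <- function(spec, n_per_class, seed = spec$seed) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  assert_that(length(n_per_class) == 1L && n_per_class >= 1,
              "n_per_class must be >= 1")
  grid <- tidyr::expand_grid(label = seq_len(spec$n_classes) - 1L,
                             rep = seq_len(as.integer(n_per_class)))
  items <- seq_len(nrow(grid))
  seeds <- vapply(items, function(i) derive_seed(seed, i), integer(1))
  rendered <- purrr::map2(grid$label, seeds,
                          function(lab, s) generate_leaf_image(spec, lab, s))
  structure(
    list(
      manifest = tibble::tibble(item = items, label = grid$label, seed = seeds),
      images = purrr::map(rendered, "image"),
      masks = purrr::map(rendered, "mask"),
      spec = spec
    ),
    class = "phantom_dataset"
  )
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d images, %d classes, %dx%d px\n",
              nrow(x$manifest), x$spec$n_classes,
              x$spec$image_size[1], x$spec$image_size[2]))
  invisible(x)
}

#' Add clipped Gaussian noise to an image
#'
#' @param image Matrix or array with values in `[0,1]`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed RNG seed.
#'
#' @return Image of the same shape, `clip(image + N(0, sigma^2), 0, 1)`.
#' @export
add_noise <- function(image, sigma, seed = 1L) {
  assert_that(is_image(image), "image must be a numeric matrix or array")
  assert_that(length(sigma) == 1L && sigma >= 0, "sigma must be non-negative")
  if (sigma == 0) return(image)
  withr::with_seed(as.integer(seed), {
    noisy <- image + array(rnorm(length(image), 0, sigma), dim(image))
  })
  clip01(noisy)
}
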