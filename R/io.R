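#' Read an image file
#'
#' Reads PNG or TIFF into a `[0,1]` numeric matrix (grayscale) or
#' `H x W x 3` array (an alpha channel, if present, is dropped).
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#'
#' @return Numeric matrix or array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_cropdx(sprintf("cannot read image: %s", path), "cropdx_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_cropdx(sprintf("unsupported image format: %s", path), "cropdx_io_error")
  )
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img
}

#' Write an image file
#'
#' @param image Matrix or `H x W x 3` array in `[0,1]`.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- clip01(image)
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
    stop_cropdx(sprintf("unsupported image format: %s", path), "cropdx_io_error")
  )
  invisible(path)
}

#' Read a label mask from a single-channel PNG
#'
#' Masks are stored with label `k` at pixel value `k/255`.
#'
#' @param path PNG path.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write a label mask as a single-channel PNG
#'
#' @param mask Integer label matrix (values 0..255).
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  assert_that(all(mask >= 0) && all(mask <= 255), "mask labels must be 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Write a phantom dataset to disk
#'
#' Images as 8-bit PNG, masks as single-channel PNG and a CSV manifest
#' with columns `path`, `mask_path`, `label`.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#'
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  paths <- sprintf("img%04d.png", man$item)
  mask_paths <- sprintf("mask%04d.png", man$item)
  for (i in seq_len(nrow(man))) {
    write_image(dataset$images[[i]], file.path(dir, paths[i]))
    write_mask(dataset$masks[[i]], file.path(dir, mask_paths[i]))
  }
  out <- data.frame(path = paths, mask_path = mask_paths, label = man$label)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(out, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Load a dataset from a CSV manifest
#'
#' The manifest must have columns `path` and `label`; `mask_path` is
#' optional.  Paths are resolved relative to the manifest location.
#'
#' @param manifest_path CSV path.
#'
#' @return A `phantom_dataset`-shaped list (`manifest`, `images`, `masks`).
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_cropdx(sprintf("cannot read manifest: %s", manifest_path),
                "cropdx_io_error")
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  assert_that(all(c("path", "label") %in% names(man)),
              "manifest needs columns path, label")
  base <- dirname(manifest_path)
  images <- lapply(man$path, function(p) read_image(file.path(base, p)))
  masks <- if ("mask_path" %in% names(man)) {
    lapply(man$mask_path, function(p) {
      if (is.na(p) || p == "") NULL else read_mask(file.path(base, p))
    })
  } else {
    rep(list(NULL), nrow(man))
  }
  list(manifest = tibble::tibble(item = seq_len(nrow(man)), label = man$label,
                                 seed = NA_integer_),
       images = images, masks = masks)
}
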