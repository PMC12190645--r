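#' Full pipeline configuration
#'
#' Bundles the per-stage configurations with the preprocessing, split and
#' training settings.  Defaults follow the reference settings: images
#' resized to 256x256 and scaled to `[0,1]`, an 80/20 stratified split,
#' diffusion with `k = 30`, `dt = 0.15`, 20 iterations, Adam at 0.001 with
#' x0.1 decay every 25 epochs throughout.
#'
#' @param target_size Integer (or length-2 vector), working image size.
#' @param split_fraction Training fraction in (0, 1).
#' @param n_classes Number of disease classes.
#' @param diffusion A [diffusion_config()].
#' @param unet A [unetpp_config()]; `NULL` builds one matching
#'   `target_size`/`n_classes`.
#' @param mgra An [mgra_config()].
#' @param glnp A [glnp_config()]; `NULL` builds one matching `n_classes`.
#' @param n_kernels Size of the convolutional feature bank.
#' @param seg_train,glnp_train Training-option lists (see
#'   [train_segmenter()], [train_classifier()]).
#' @param augment_ops Character vector of augmentation ops applied to the
#'   training split (subset of `"rotate90s"`, `"hflip"`, `"vflip"`,
#'   `"scale"`); empty for none.
#' @param seed Master seed fixing the split, initializations and optimizer
#'   shuffles.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_size = 256L, split_fraction = 0.8,
                            n_classes = 3L,
                            diffusion = diffusion_config(),
                            unet = NULL, mgra = mgra_config(),
                            glnp = NULL, n_kernels = 64L,
                            seg_train = list(), glnp_train = list(),
                            augment_ops = character(0), seed = 1L) {
  assert_that(split_fraction > 0 && split_fraction < 1,
              "split_fraction must lie in (0,1)")
  if (length(target_size) == 1L) target_size <- rep(as.integer(target_size), 2L)
  assert_that(all(target_size > 0), "target_size must be positive")
  if (is.null(unet)) {
    unet <- unetpp_config(depth = 4L, filters = c(32L, 64L, 128L, 256L),
                          in_channels = 1L, n_classes = n_classes + 2L,
                          seed = seed)
  }
  if (is.null(glnp)) {
    glnp <- glnp_config(n_classes = n_classes, seed = seed)
  }
  structure(list(target_size = target_size, split_fraction = split_fraction,
                 n_classes = as.integer(n_classes), diffusion = diffusion,
                 unet = unet, mgra = mgra, glnp = glnp,
                 n_kernels = as.integer(n_kernels),
                 seg_train = seg_train, glnp_train = glnp_train,
                 augment_ops = augment_ops, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Preprocess an image
#'
#' Bilinear resize to the target size and intensity normalization to
#' `[0,1]` (8-bit inputs are divided by 255).  Idempotent: preprocessing an
#' already-preprocessed image returns it unchanged.
#'
#' @param image Matrix or `H x W x C` array.
#' @param target_size Length-1 or -2 integer size.
#'
#' @return The preprocessed image.
#' @export
preprocess <- function(image, target_size = 256L) {
  assert_that(is_image(image), "image must be a numeric matrix or array")
  if (length(target_size) == 1L) target_size <- rep(target_size, 2L)
  if (max(image) > 1.5) image <- image / 255
  image <- clip01(image)
  resize_bilinear(image, target_size[1], target_size[2])
}

#' Stratified train/test split of a phantom dataset
#'
#' @param dataset A `phantom_dataset` (or list with `manifest`, `images`,
#'   `masks`).
#' @param fraction Training fraction.
#' @param seed Split seed.
#'
#' @return List with `train` and `test` datasets (same structure, disjoint
#'   manifests whose union is the input).
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 1L) {
  man <- dataset$manifest
  assert_that(nrow(man) > 0, "dataset is empty")
  assert_that(fraction > 0 && fraction < 1, "fraction must lie in (0,1)")
  counts <- table(man$label)
  if (any(counts < 2)) {
    warning("a class has fewer than 2 items; falling back to a plain split")
    train_rows <- withr::with_seed(as.integer(seed), {
      sample(seq_len(nrow(man)), max(1L, round(fraction * nrow(man))))
    })
  } else {
    train_rows <- withr::with_seed(as.integer(seed), {
      unlist(lapply(split(seq_len(nrow(man)), man$label), function(ix) {
        sample(ix, max(1L, round(fraction * length(ix))))
      }), use.names = FALSE)
    })
  }
  train_rows <- sort(train_rows)
  test_rows <- setdiff(seq_len(nrow(man)), train_rows)
  take <- function(rows) {
    out <- dataset
    out$manifest <- man[rows, , drop = FALSE]
    out$images <- dataset$images[rows]
    out$masks <- dataset$masks[rows]
    out
  }
  list(train = take(train_rows), test = take(test_rows))
}

#' Augment an image/mask pair
#'
#' Applies the requested geometric augmentations, transforming the mask
#' identically (nearest-neighbour for labels); the original pair is always
#' retained as the first element.
#'
#' @param image Matrix or RGB array.
#' @param mask Integer label matrix (or `NULL`).
#' @param ops Subset of `"rotate90s"` (adds 90/180/270 degree rotations),
#'   `"hflip"`, `"vflip"`, `"scale"` (one random factor in `[0.9, 1.1]`,
#'   re-cropped/padded to the input size).
#' @param seed RNG seed (used by `"scale"`).
#'
#' @return List of `list(image =, mask =)` pairs.
#' @export
augment <- function(image, mask = NULL, ops = c("rotate90s", "hflip", "vflip"),
                    seed = 1L) {
  bad <- setdiff(ops, c("rotate90s", "hflip", "vflip", "scale"))
  if (length(bad) > 0) {
    stop_cropdx(sprintf("unknown augmentation op: %s", paste(bad, collapse = ", ")),
                "cropdx_config_error")
  }
  out <- list(list(image = image, mask = mask))
  apply_both <- function(f_img, f_mask) {
    list(image = f_img(image), mask = if (is.null(mask)) NULL else f_mask(mask))
  }
  rot90 <- function(x) {
    if (length(dim(x)) == 2L) t(x)[, nrow(x):1, drop = FALSE]
    else {
      d <- dim(x)
      y <- array(0, c(d[2], d[1], d[3]))
      for (ch in seq_len(d[3])) y[, , ch] <- t(x[, , ch])[, d[1]:1]
      y
    }
  }
  flip_h <- function(x) {
    if (length(dim(x)) == 2L) x[, ncol(x):1, drop = FALSE]
    else x[, dim(x)[2]:1, , drop = FALSE]
  }
  flip_v <- function(x) {
    if (length(dim(x)) == 2L) x[nrow(x):1, , drop = FALSE]
    else x[dim(x)[1]:1, , , drop = FALSE]
  }
  if ("rotate90s" %in% ops) {
    r1 <- apply_both(rot90, rot90)
    r2 <- list(image = rot90(r1$image),
               mask = if (is.null(mask)) NULL else rot90(r1$mask))
    r3 <- list(image = rot90(r2$image),
               mask = if (is.null(mask)) NULL else rot90(r2$mask))
    out <- c(out, list(r1, r2, r3))
  }
  if ("hflip" %in% ops) out <- c(out, list(apply_both(flip_h, flip_h)))
  if ("vflip" %in% ops) out <- c(out, list(apply_both(flip_v, flip_v)))
  if ("scale" %in% ops) {
    factor <- withr::with_seed(as.integer(seed), runif(1, 0.9, 1.1))
    out <- c(out, list(scale_pair(image, mask, factor)))
  }
  out
}

# Rescale then centre-crop/pad back to the original size; nearest-neighbour
# resampling for the label mask.
scale_pair <- function(image, mask, factor) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  h2 <- max(1L, round(h * factor)); w2 <- max(1L, round(w * factor))
  img2 <- resize_bilinear(image, h2, w2)
  msk2 <- if (is.null(mask)) NULL else resize_nearest(mask, h2, w2)
  fit <- function(x, fill) {
    dd <- dim(x)
    out_dim <- if (length(dd) == 2L) c(h, w) else c(h, w, dd[3])
    out <- array(fill, out_dim)
    ro <- max(0L, (h - dd[1]) %/% 2L); co <- max(0L, (w - dd[2]) %/% 2L)
    ri <- max(0L, (dd[1] - h) %/% 2L); ci <- max(0L, (dd[2] - w) %/% 2L)
    nr <- min(h, dd[1]); nc <- min(w, dd[2])
    if (length(dd) == 2L) {
      out[ro + seq_len(nr), co + seq_len(nc)] <-
        x[ri + seq_len(nr), ci + seq_len(nc)]
    } else {
      out[ro + seq_len(nr), co + seq_len(nc), ] <-
        x[ri + seq_len(nr), ci + seq_len(nc), , drop = FALSE]
    }
    if (length(dd) == 2L && is.integer(x)) matrix(as.integer(out), h, w) else out
  }
  list(image = fit(img2, 0), mask = if (is.null(mask)) NULL else fit(msk2, 0L))
}

resize_nearest <- function(m, h2, w2) {
  ri <- pmin(pmax(round((seq_len(h2) - 0.5) * nrow(m) / h2 + 0.5), 1L), nrow(m))
  ci <- pmin(pmax(round((seq_len(w2) - 0.5) * ncol(m) / w2 + 0.5), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Multiclass evaluation report
#'
#' Accuracy, macro-averaged precision/recall/F1 (per-class one-vs-rest
#' before averaging; F1 is the per-class harmonic mean) and macro
#' one-vs-rest AUC from the probability scores (trapezoidal ROC rule).
#' All rates are percentages in `[0, 100]`.
#'
#' @param predicted Integer predicted labels (0-based).
#' @param truth Integer true labels, same length.
#' @param scores Optional matrix of per-class probabilities (rows =
#'   samples); required for AUC.
#'
#' @return An object of class `cropdx_eval`: list with `summary` (tibble:
#'   accuracy, precision, recall, f1, auc), `per_class` tibble and the
#'   `confusion` matrix.
#' @export
evaluate <- function(predicted, truth, scores = NULL) {
  assert_that(length(predicted) == length(truth),
              "predicted and truth must be aligned")
  classes <- sort(unique(c(predicted, truth)))
  K <- length(classes)
  conf <- matrix(0L, K, K, dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(truth)) {
    conf[as.character(truth[i]), as.character(predicted[i])] <-
      conf[as.character(truth[i]), as.character(predicted[i])] + 1L
  }
  acc <- mean(predicted == truth)
  present <- classes[classes %in% truth]
  absent <- setdiff(classes, present)
  if (length(absent) > 0) {
    warning(sprintf("class(es) absent from truth excluded from macro average: %s",
                    paste(absent, collapse = ", ")))
  }
  per <- lapply(present, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    auc <- NA_real_
    if (!is.null(scores)) {
      col <- which(classes == cl)
      auc <- binary_auc(scores[, col], truth == cl)
    }
    tibble::tibble(class = cl, precision = 100 * prec, recall = 100 * rec,
                   f1 = 100 * f1, auc = 100 * auc)
  })
  per <- dplyr::bind_rows(per)
  summary <- tibble::tibble(
    accuracy = 100 * acc,
    precision = mean(per$precision),
    recall = mean(per$recall),
    f1 = mean(per$f1),
    auc = if (is.null(scores)) NA_real_ else mean(per$auc)
  )
  structure(list(summary = summary, per_class = per, confusion = conf),
            class = "cropdx_eval")
}

# One-vs-rest AUC by the trapezoidal rule over the empirical ROC curve
# (ties handled by grouping equal scores).
binary_auc <- function(score, positive) {
  pos <- sum(positive)
  neg <- sum(!positive)
  if (pos == 0 || neg == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- positive[ord]
  groups <- cumsum(!duplicated(s))
  tp <- tapply(y, groups, sum)
  fp <- tapply(!y, groups, sum)
  tpr <- c(0, cumsum(tp) / pos)
  fpr <- c(0, cumsum(fp) / neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.cropdx_eval <- function(x, ...) {
  cat("<cropdx_eval>\n")
  print(as.data.frame(round(x$summary, 2)))
  invisible(x)
}

#' Run the complete diagnosis pipeline on a phantom dataset
#'
#' Executes every stage in sequence: preprocessing, adaptive anisotropic
#' diffusion, fuzzy U-Net++ training and segmentation, convolutional
#' feature extraction over lesion-masked images, gorilla/remora feature
#' selection on the training split, feature-graph construction, GLNP
#' training and final evaluation on the held-out split.  Per-stage tables
#' (denoising, segmentation, selection and classification reports) are
#' collected along the way.  A single master seed fixes the split and all
#' stochastic optimizers.
#'
#' @param dataset A `phantom_dataset` (images + masks + manifest).
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#' @param log_file Optional path; the per-stage log (stage, parameters,
#'   seed, wall time) is additionally written there as plain text.
#'
#' @return An object of class `cropdx_run`: list with `evaluation`
#'   (a `cropdx_eval` on the test split), `reports` (tibbles
#'   `denoising`, `segmentation`, `selection`, `classification`), the
#'   fitted `segmenter` and `classifier`, `selected` feature indices,
#'   `graph`, `membership` parameters and `config`.
#' @export
run_pipeline <- function(dataset, cfg = pipeline_config(), verbose = FALSE,
                         log_file = NULL) {
  say <- function(...) if (verbose) message(sprintf(...))
  log_rows <- list()
  t_stage <- proc.time()[3]
  log_stage <- function(stage, detail, seed = NA_integer_) {
    now <- proc.time()[3]
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      stage = stage, detail = detail, seed = as.integer(seed),
      wall_time_s = round(now - t_stage, 3))
    t_stage <<- now
  }
  assert_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  n <- length(dataset$images)
  assert_that(n > 0, "dataset is empty")
  assert_that(length(dataset$masks) == n,
              "training requires a mask for every image")
  for (i in seq_len(n)) {
    if (is.null(dataset$masks[[i]])) {
      stop_cropdx(sprintf("missing mask for item %d", dataset$manifest$item[i]),
                  "cropdx_stage_error")
    }
  }
  K_seg <- cfg$unet$n_classes

  say("preprocess: resizing %d images to %dx%d", n,
      cfg$target_size[1], cfg$target_size[2])
  images <- lapply(dataset$images, preprocess, target_size = cfg$target_size)
  masks <- lapply(dataset$masks, function(m) {
    if (all(dim(m) == cfg$target_size)) m else
      resize_nearest(m, cfg$target_size[1], cfg$target_size[2])
  })

  log_stage("preprocess", sprintf("%d images -> %dx%d", n, cfg$target_size[1], cfg$target_size[2]))
  say("denoise: adaptive anisotropic diffusion (k=%g, %d iterations)",
      cfg$diffusion$k, cfg$diffusion$n_iter)
  den <- denoise_report(images, cfg$diffusion,
                        ids = sprintf("Img%02d", dataset$manifest$item))
  den_images <- den$denoised

  log_stage("denoise", sprintf("k=%g dt=%g n_iter=%d", cfg$diffusion$k, cfg$diffusion$dt, cfg$diffusion$n_iter))

  work <- dataset
  work$images <- den_images
  work$masks <- masks
  sp <- split_dataset(work, cfg$split_fraction, seed = derive_seed(cfg$seed, 1L))
  train <- sp$train
  test <- sp$test

  if (length(cfg$augment_ops) > 0) {
    say("augment: %s", paste(cfg$augment_ops, collapse = ", "))
    aug_imgs <- list(); aug_masks <- list(); aug_labels <- integer(0)
    for (i in seq_along(train$images)) {
      pairs <- augment(train$images[[i]], train$masks[[i]], cfg$augment_ops,
                       seed = derive_seed(cfg$seed, 100L + i))
      for (p in pairs) {
        aug_imgs[[length(aug_imgs) + 1L]] <- p$image
        aug_masks[[length(aug_masks) + 1L]] <- p$mask
        aug_labels <- c(aug_labels, train$manifest$label[i])
      }
    }
    train$images <- aug_imgs
    train$masks <- aug_masks
    train$manifest <- tibble::tibble(item = seq_along(aug_imgs),
                                     label = aug_labels,
                                     seed = NA_integer_)
  }

  log_stage("split", sprintf("train=%d test=%d", length(train$images), length(test$images)), derive_seed(cfg$seed, 1L))
  say("fuzzyseg: fitting memberships and training U-Net++ (%d train images)",
      length(train$images))
  mp <- fit_membership_params(train$images, train$masks, K_seg)
  segmenter <- train_segmenter(train, cfg$unet, cfg$seg_train,
                               seed = derive_seed(cfg$seed, 2L))

  log_stage("train_segmenter", sprintf("depth=%d epochs=%s", cfg$unet$depth, toString(segmenter$loss_history |> length())), derive_seed(cfg$seed, 2L))
  seg_all <- function(ds) lapply(ds$images, segment, model = segmenter, mp = mp)
  say("fuzzyseg: segmenting")
  seg_train_maps <- seg_all(train)
  seg_test_maps <- seg_all(test)
  seg_report <- dplyr::bind_rows(lapply(seq_along(seg_test_maps), function(i) {
    m <- segmentation_metrics(seg_test_maps[[i]], test$masks[[i]], K_seg)
    tibble::tibble(image_id = sprintf("Img%02d", test$manifest$item[i]),
                   segmentation_accuracy = 100 * m$accuracy,
                   mean_iou = m$mean_iou, fuzzy_overlap = m$fuzzy_overlap)
  }))

  log_stage("segment", sprintf("%d images", n))
  say("mgra: extracting %d convolutional features", cfg$n_kernels)
  bank <- kernel_bank(cfg$n_kernels, seed = derive_seed(cfg$seed, 3L))
  masked_lum <- function(img, seg) luminance(img) * (seg$labels >= 2)
  feat_of <- function(ds, maps) {
    t(vapply(seq_along(ds$images),
             function(i) conv_features(masked_lum(ds$images[[i]], maps[[i]]), bank),
             numeric(cfg$n_kernels)))
  }
  X_train <- feat_of(train, seg_train_maps)
  X_test <- feat_of(test, seg_test_maps)

  log_stage("conv_features", sprintf("%d kernels", cfg$n_kernels), derive_seed(cfg$seed, 3L))
  say("mgra: selecting features (pop %d, %d generations)",
      cfg$mgra$population, cfg$mgra$generations)
  mg_cfg <- cfg$mgra
  mg_cfg$seed <- derive_seed(cfg$seed, 4L)
  sel <- select_features(X_train, train$manifest$label, mg_cfg)
  sel_report <- tibble::tibble(
    dataset_id = "train",
    initial_feature_count = sel$initial_count,
    selected_feature_count = sel$selected_count,
    selection_ratio = sel$selection_ratio
  )

  log_stage("select_features", sprintf("pop=%d gens=%d selected=%d", cfg$mgra$population, cfg$mgra$generations, sel$selected_count), derive_seed(cfg$seed, 4L))
  say("glnp: building feature graph and training classifier")
  gl_cfg <- cfg$glnp
  gl_cfg$seed <- derive_seed(cfg$seed, 5L)
  # Edges encode the feature correlations: cosine similarity of *centered*
  # profiles is exactly the Pearson correlation.  Zero-variance profiles
  # (e.g. zero-sum derivative kernels, whose globally averaged response
  # vanishes) carry no signal and have no defined similarity: drop them
  # from the selected set first.
  centered <- scale(X_train[, sel$selected, drop = FALSE], scale = FALSE)
  keep <- sqrt(colSums(centered^2)) > 0
  sel$selected <- sel$selected[keep]
  if (length(sel$selected) < 2L) {
    vars <- apply(X_train, 2L, stats::var)
    sel$selected <- order(vars, decreasing = TRUE)[1:2]
  }
  profiles <- scale(X_train[, sel$selected, drop = FALSE], scale = FALSE)
  graph <- build_graph(profiles, gl_cfg)
  classifier <- train_classifier(X_train[, sel$selected, drop = FALSE],
                                 train$manifest$label, graph, gl_cfg,
                                 cfg$glnp_train,
                                 seed = derive_seed(cfg$seed, 6L))

  log_stage("train_classifier", sprintf("%d nodes", graph$n_nodes), derive_seed(cfg$seed, 6L))
  preds <- predict(classifier, X_test[, sel$selected, drop = FALSE])
  scores <- do.call(rbind, preds$probs)
  evaluation <- evaluate(preds$predicted, test$manifest$label, scores)
  class_report <- tibble::tibble(
    image_id = sprintf("Img%02d", test$manifest$item),
    predicted_class = preds$predicted,
    classification_confidence = 100 * preds$confidence,
    true_class = test$manifest$label,
    correct = preds$predicted == test$manifest$label
  )

  log_stage("evaluate", sprintf("%d test images", nrow(test$manifest)))
  stage_log <- dplyr::bind_rows(log_rows)
  if (!is.null(log_file)) {
    utils::write.table(stage_log, log_file, row.names = FALSE, quote = FALSE,
                       sep = "\t")
  }

  structure(list(
    evaluation = evaluation,
    reports = list(denoising = dplyr::select(den, -"denoised"),
                   segmentation = seg_report,
                   selection = sel_report,
                   classification = class_report),
    segmenter = segmenter, classifier = classifier,
    selected = sel$selected, selection = sel, graph = graph,
    membership = mp, config = cfg, log = stage_log,
    split = list(train_items = train$manifest$item,
                 test_items = test$manifest$item)
  ), class = "cropdx_run")
}

#' @export
print.cropdx_run <- function(x, ...) {
  cat(sprintf("<cropdx_run> %d selected features; test metrics:\n",
              length(x$selected)))
  print(as.data.frame(round(x$evaluation$summary, 2)))
  invisible(x)
}
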