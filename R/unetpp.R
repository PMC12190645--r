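#' Configuration of the nested U-Net++ segmenter
#'
#' @param depth Number of resolution levels (>= 1); default 4.
#' @param filters Integer vector of per-level channel counts,
#'   `length(filters) == depth`; default `c(32, 64, 128, 256)`.
#' @param in_channels Input channels (1 = luminance, 3 = RGB).
#' @param n_classes Number of segmentation classes (background, healthy
#'   tissue and one class per disease).
#' @param seed Weight-initialization seed.
#'
#' @return An object of class `unetpp_config`.
#' @export
unetpp_config <- function(depth = 4L, filters = c(32L, 64L, 128L, 256L),
                          in_channels = 1L, n_classes = 4L, seed = 1L) {
  depth <- as.integer(depth)
  assert_that(depth >= 1, "depth must be >= 1")
  assert_that(length(filters) == depth,
              "length(filters) must equal depth")
  assert_that(all(filters > 0), "all filter counts must be positive")
  assert_that(in_channels >= 1, "in_channels must be >= 1")
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  structure(list(depth = depth, filters = as.integer(filters),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "unetpp_config")
}

# Node lattice in creation (topological) order: encoder column j = 0 from
# the top row down, then skip columns j = 1 .. depth-1.  Node (i, j) with
# j >= 1 consumes the concatenation of all same-row predecessors
# X(i, 0..j-1) and the 2x-upsampled X(i+1, j-1).
unetpp_nodes <- function(depth) {
  nodes <- list()
  for (i in seq_len(depth) - 1L) nodes[[length(nodes) + 1L]] <- c(i, 0L)
  for (j in seq_len(depth - 1L)) {
    for (i in 0:(depth - 1L - j)) nodes[[length(nodes) + 1L]] <- c(i, j)
  }
  nodes
}

node_key <- function(i, j) paste0("n", i, "_", j)

node_in_channels <- function(cfg, i, j) {
  f <- cfg$filters
  if (j == 0L) {
    if (i == 0L) cfg$in_channels else f[i]
  } else {
    j * f[i + 1L] + f[i + 2L]
  }
}

#' Build a fuzzy U-Net++ model
#'
#' Constructs the nested encoder--decoder lattice: every node is a block of
#' two (3x3 convolution, batch norm, ReLU) stages; downsampling is 2x2 max
#' pooling, upsampling is bilinear.  A shared 1x1 convolution head maps
#' top-row node features to per-class logits; at inference the same head
#' scores every top-row node so Mamdani rules can fuse the nested skip
#' pathway ([segment()]).  Initialization is He-scaled Gaussian,
#' deterministic in `cfg$seed`.
#'
#' @param cfg A [unetpp_config()].
#'
#' @return An object of class `unetpp_model` with untrained weights.
#' @export
build_unetpp <- function(cfg) {
  assert_that(inherits(cfg, "unetpp_config"), "cfg must be a unetpp_config")
  f <- cfg$filters
  params <- list()
  bn <- list()
  withr::with_seed(cfg$seed, {
    for (nd in unetpp_nodes(cfg$depth)) {
      i <- nd[1]; j <- nd[2]
      cin <- node_in_channels(cfg, i, j)
      cout <- f[i + 1L]
      key <- node_key(i, j)
      params[[paste0(key, "_W1")]] <-
        array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), c(3, 3, cin, cout))
      params[[paste0(key, "_b1")]] <- numeric(cout)
      params[[paste0(key, "_g1")]] <- rep(1, cout)
      params[[paste0(key, "_be1")]] <- numeric(cout)
      params[[paste0(key, "_W2")]] <-
        array(rnorm(9 * cout * cout, 0, sqrt(2 / (9 * cout))), c(3, 3, cout, cout))
      params[[paste0(key, "_b2")]] <- numeric(cout)
      params[[paste0(key, "_g2")]] <- rep(1, cout)
      params[[paste0(key, "_be2")]] <- numeric(cout)
      bn[[key]] <- list(
        c1 = list(mean = numeric(cout), var = rep(1, cout)),
        c2 = list(mean = numeric(cout), var = rep(1, cout))
      )
    }
    params[["head_W"]] <- matrix(rnorm(f[1] * cfg$n_classes, 0, sqrt(2 / f[1])),
                                 f[1], cfg$n_classes)
    params[["head_b"]] <- numeric(cfg$n_classes)
  })
  structure(list(cfg = cfg, params = params, bn = bn,
                 loss_history = numeric(0), trained = FALSE),
            class = "unetpp_model")
}

#' Number of trainable parameters of a U-Net++ model
#'
#' @param model A `unetpp_model`.
#' @return Integer count of all weights, biases and batch-norm parameters.
#' @export
unetpp_param_count <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.unetpp_model <- function(x, ...) {
  cat(sprintf("<unetpp_model> depth %d, filters [%s], %d classes, %s, %d parameters\n",
              x$cfg$depth, paste(x$cfg$filters, collapse = ", "),
              x$cfg$n_classes, if (x$trained) "trained" else "untrained",
              unetpp_param_count(x)))
  invisible(x)
}

# Forward pass of one conv-bn-relu x2 block.
block_forward <- function(X, params, key, bn_node, training) {
  c1 <- conv3x3_forward(X, params[[paste0(key, "_W1")]], params[[paste0(key, "_b1")]])
  b1 <- bn_forward(c1$out, params[[paste0(key, "_g1")]], params[[paste0(key, "_be1")]],
                   bn_node$c1, training)
  r1 <- relu_forward(b1$out)
  c2 <- conv3x3_forward(r1$out, params[[paste0(key, "_W2")]], params[[paste0(key, "_b2")]])
  b2 <- bn_forward(c2$out, params[[paste0(key, "_g2")]], params[[paste0(key, "_be2")]],
                   bn_node$c2, training)
  r2 <- relu_forward(b2$out)
  list(out = r2$out,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2),
       bn_node = list(c1 = b1$running, c2 = b2$running))
}

block_backward <- function(dOut, cache, params, key) {
  dr2 <- relu_backward(dOut, cache$r2$mask)
  bb2 <- bn_backward(dr2, cache$b2, params[[paste0(key, "_g2")]])
  cb2 <- conv3x3_backward(bb2$dX, cache$c2$Xp, params[[paste0(key, "_W2")]])
  dr1 <- relu_backward(cb2$dX, cache$r1$mask)
  bb1 <- bn_backward(dr1, cache$b1, params[[paste0(key, "_g1")]])
  cb1 <- conv3x3_backward(bb1$dX, cache$c1$Xp, params[[paste0(key, "_W1")]])
  grads <- list()
  grads[[paste0(key, "_W1")]] <- cb1$dW
  grads[[paste0(key, "_b1")]] <- cb1$db
  grads[[paste0(key, "_g1")]] <- bb1$dgamma
  grads[[paste0(key, "_be1")]] <- bb1$dbeta
  grads[[paste0(key, "_W2")]] <- cb2$dW
  grads[[paste0(key, "_b2")]] <- cb2$db
  grads[[paste0(key, "_g2")]] <- bb2$dgamma
  grads[[paste0(key, "_be2")]] <- bb2$dbeta
  list(dX = cb1$dX, grads = grads)
}

# Full lattice forward.  X: (H, W, N, in_channels).  Returns node outputs,
# per-node caches (when `keep_cache`), head logits of the final top-row
# node, and head logits of every top-row node (inference fuzzy scoring).
unetpp_forward <- function(model, X, training = FALSE, keep_cache = training) {
  cfg <- model$cfg
  d <- dim(X)
  div <- 2^(cfg$depth - 1L)
  assert_that(d[1] %% div == 0 && d[2] %% div == 0,
              sprintf("input size must be divisible by %d for depth %d",
                      div, cfg$depth))
  assert_that(d[4] == cfg$in_channels,
              "input channel count does not match model configuration")
  outs <- list()
  caches <- list()
  pool_caches <- list()
  for (nd in unetpp_nodes(cfg$depth)) {
    i <- nd[1]; j <- nd[2]
    key <- node_key(i, j)
    if (j == 0L) {
      if (i == 0L) {
        inp <- X
      } else {
        mp <- maxpool2_forward(outs[[node_key(i - 1L, 0L)]])
        pool_caches[[key]] <- list(masks = mp$masks,
                                   dimX = dim(outs[[node_key(i - 1L, 0L)]]))
        inp <- mp$out
      }
      sources <- NULL
    } else {
      parts <- lapply(0:(j - 1L), function(jj) outs[[node_key(i, jj)]])
      up_in <- outs[[node_key(i + 1L, j - 1L)]]
      parts[[j + 1L]] <- upsample2_forward(up_in)
      inp <- concat_channels(parts)
      sources <- list(widths = vapply(parts, function(p) dim(p)[4], integer(1)),
                      up_dim = dim(up_in))
    }
    bf <- block_forward(inp, model$params, key, model$bn[[key]], training)
    if (training) model$bn[[key]] <- bf$bn_node
    outs[[key]] <- bf$out
    if (keep_cache) {
      caches[[key]] <- list(block = bf$cache, sources = sources,
                            inp_dim = dim(inp))
    }
  }
  top <- node_key(0L, cfg$depth - 1L)
  head <- conv1x1_forward(outs[[top]], model$params$head_W, model$params$head_b)
  row0_logits <- NULL
  if (!training) {
    row0_logits <- lapply(0:(cfg$depth - 1L), function(j) {
      conv1x1_forward(outs[[node_key(0L, j)]], model$params$head_W,
                      model$params$head_b)$out
    })
  }
  list(logits = head$out, outs = outs, caches = caches, pool = pool_caches,
       head_in = outs[[top]], row0_logits = row0_logits, model = model)
}

# Full lattice backward from dlogits; returns the gradient list.
unetpp_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg
  grads <- list()
  top <- node_key(0L, cfg$depth - 1L)
  hb <- conv1x1_backward(dlogits, fwd$head_in, model$params$head_W)
  grads[["head_W"]] <- hb$dW
  grads[["head_b"]] <- hb$db
  dOut <- list()
  dOut[[top]] <- hb$dX
  nodes <- rev(unetpp_nodes(cfg$depth))
  for (nd in nodes) {
    i <- nd[1]; j <- nd[2]
    key <- node_key(i, j)
    dcur <- dOut[[key]]
    if (is.null(dcur)) dcur <- array(0, dim(fwd$outs[[key]]))
    bb <- block_backward(dcur, fwd$caches[[key]]$block, model$params, key)
    grads[names(bb$grads)] <- Map(function(a, b) if (is.null(a)) b else a + b,
                                  grads[names(bb$grads)], bb$grads)
    src <- fwd$caches[[key]]$sources
    if (is.null(src)) {
      if (i > 0L) {
        pc <- fwd$pool[[key]]
        prev <- node_key(i - 1L, 0L)
        dprev <- maxpool2_backward(bb$dX, pc$masks, pc$dimX)
        dOut[[prev]] <- if (is.null(dOut[[prev]])) dprev else dOut[[prev]] + dprev
      }
      # i == 0, j == 0: gradient w.r.t. the input image is discarded
    } else {
      pieces <- split_channels(bb$dX, src$widths)
      for (jj in 0:(j - 1L)) {
        skey <- node_key(i, jj)
        dOut[[skey]] <- if (is.null(dOut[[skey]])) pieces[[jj + 1L]] else
          dOut[[skey]] + pieces[[jj + 1L]]
      }
      dup <- upsample2_backward(pieces[[j + 1L]], src$up_dim)
      ukey <- node_key(i + 1L, j - 1L)
      dOut[[ukey]] <- if (is.null(dOut[[ukey]])) dup else dOut[[ukey]] + dup
    }
  }
  grads
}
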