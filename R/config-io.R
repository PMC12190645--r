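#' Write a pipeline configuration to a plain-text (YAML) file
#'
#' All scalar stage parameters are serialized.  The remora attachment
#' schedule is a function and is stored only by its default marker; a
#' config read back from disk always carries the default linear-decay
#' schedule.
#'
#' @param cfg A [pipeline_config()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  assert_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  plain <- list(
    target_size = as.integer(cfg$target_size),
    split_fraction = cfg$split_fraction,
    n_classes = cfg$n_classes,
    n_kernels = cfg$n_kernels,
    augment_ops = as.list(cfg$augment_ops),
    seed = cfg$seed,
    diffusion = cfg$diffusion[c("k", "lambda", "dt", "n_iter", "tol", "window")],
    unet = cfg$unet[c("depth", "filters", "in_channels", "n_classes", "seed")],
    mgra = cfg$mgra[c("population", "generations", "alpha", "beta", "seed")],
    glnp = cfg$glnp[c("n_layers", "widths", "edge_threshold", "n_classes",
                      "node_identity", "seed")],
    seg_train = cfg$seg_train,
    glnp_train = cfg$glnp_train
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path File written by [write_pipeline_config()].
#'
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_cropdx(sprintf("cannot read config: %s", path), "cropdx_io_error")
  }
  y <- yaml::read_yaml(path)
  pipeline_config(
    target_size = unlist(y$target_size),
    split_fraction = y$split_fraction,
    n_classes = y$n_classes,
    diffusion = do.call(diffusion_config, y$diffusion),
    unet = unetpp_config(depth = y$unet$depth,
                         filters = unlist(y$unet$filters),
                         in_channels = y$unet$in_channels,
                         n_classes = y$unet$n_classes,
                         seed = y$unet$seed),
    mgra = do.call(mgra_config, y$mgra),
    glnp = do.call(glnp_config, c(y$glnp[setdiff(names(y$glnp), "widths")],
                                  list(widths = unlist(y$glnp$widths)))),
    n_kernels = y$n_kernels,
    seg_train = y$seg_train,
    glnp_train = y$glnp_train,
    augment_ops = unlist(y$augment_ops) %||% character(0),
    seed = y$seed
  )
}
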