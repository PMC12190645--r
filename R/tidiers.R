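# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy the optimization history of a feature-selection run
#'
#' @param x An `mgra_result`.
#' @param ... Unused.
#'
#' @return A tibble with `generation` (0 = initial population) and
#'   `best_fitness`.
#' @export
tidy.mgra_result <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$history) - 1L,
                 best_fitness = x$history)
}

#' One-row summary of a feature-selection run
#'
#' @param x An `mgra_result`.
#' @param ... Unused.
#'
#' @return A tibble with the selection counts, ratio and best fitness.
#' @export
glance.mgra_result <- function(x, ...) {
  tibble::tibble(initial_feature_count = x$initial_count,
                 selected_feature_count = x$selected_count,
                 selection_ratio = x$selection_ratio,
                 best_fitness = x$best_fitness)
}

#' Tidy the training history of a segmenter
#'
#' @param x A `unetpp_model`.
#' @param ... Unused.
#'
#' @return A tibble with `epoch` and `loss`.
#' @export
tidy.unetpp_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a segmenter
#'
#' @param x A `unetpp_model`.
#' @param ... Unused.
#' @return A tibble with depth, parameter count and final loss.
#' @export
glance.unetpp_model <- function(x, ...) {
  tibble::tibble(depth = x$cfg$depth,
                 n_parameters = unetpp_param_count(x),
                 trained = x$trained,
                 final_loss = if (length(x$loss_history))
                   x$loss_history[length(x$loss_history)] else NA_real_)
}

#' Tidy the training history of a GLNP classifier
#'
#' @param x A `glnp_model`.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @export
tidy.glnp_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' Tidy per-class evaluation metrics
#'
#' @param x A `cropdx_eval`.
#' @param ... Unused.
#' @return The per-class metric tibble.
#' @export
tidy.cropdx_eval <- function(x, ...) x$per_class

#' One-row evaluation summary
#'
#' @param x A `cropdx_eval`.
#' @param ... Unused.
#' @return A tibble with accuracy, precision, recall, f1 and auc (all
#'   percentages).
#' @export
glance.cropdx_eval <- function(x, ...) x$summary

#' @rdname glance.cropdx_eval
#' @export
glance.cropdx_run <- function(x, ...) x$evaluation$summary

#' Plot a segmentation map
#'
#' Raster plot of the crisp labels.
#'
#' @param object A `segmentation_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmentation_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$labels)),
                           col = seq_len(ncol(object$labels)))
  df$label <- factor(object$labels[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a feature-selection history
#'
#' @param object An `mgra_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mgra_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best fitness J") +
    ggplot2::theme_minimal()
}

#' Plot a training loss curve
#'
#' @param object A `unetpp_model` or `glnp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unetpp_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.unetpp_model
#' @export
autoplot.glnp_model <- autoplot.unetpp_model

#' Plot an evaluation confusion matrix
#'
#' @param object A `cropdx_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cropdx_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}
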