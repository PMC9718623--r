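#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a butterfly-optimization selection
#'
#' @param x A `boa_selection`.
#' @param ... Unused.
#' @return Tibble with `feature_id` and `selected`.
#' @method tidy boa_selection
#' @export
tidy.boa_selection <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_ids,
                 selected = x$mask == 1L)
}

#' @rdname tidy.boa_selection
#' @return For `glance`: a one-row tibble with `n_selected`, `n_features`,
#'   `best_fitness`, `n_iters`.
#' @method glance boa_selection
#' @export
glance.boa_selection <- function(x, ...) {
  tibble::tibble(n_selected = x$n_selected,
                 n_features = length(x$mask),
                 best_fitness = x$best_fitness,
                 n_iters = length(x$best_fitness_trace) - 1L)
}

#' Plot the best-fitness trace of a selection run
#'
#' @param object A `boa_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boa_selection
#' @export
autoplot.boa_selection <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$best_fitness_trace) - 1L,
                       best_fitness = object$best_fitness_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness (lower is better)",
                  title = "Improved BOA best-fitness trace") +
    ggplot2::theme_minimal()
}

#' Tidy a fusion report
#'
#' @param x A `fusion_report`.
#' @param ... Unused.
#' @return Tibble with `feature_id`, `status`
#'   (`kept` / `dropped_redundant` / `dropped_uncorroborated`) and `detail`.
#' @method tidy fusion_report
#' @export
tidy.fusion_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(feature_id = x$kept_ids, status = "kept",
                   detail = NA_real_),
    tibble::tibble(feature_id = x$dropped_redundant$dropped_id,
                   status = "dropped_redundant",
                   detail = x$dropped_redundant$r),
    tibble::tibble(feature_id = x$dropped_low$id,
                   status = "dropped_uncorroborated",
                   detail = x$dropped_low$max_abs_r)
  )
}

#' @rdname tidy.fusion_report
#' @method glance fusion_report
#' @export
glance.fusion_report <- function(x, ...) {
  tibble::tibble(fused_dim = x$fused_dim,
                 n_dropped_redundant = nrow(x$dropped_redundant),
                 n_dropped_uncorroborated = nrow(x$dropped_low))
}

#' Tidy a panel evaluation
#'
#' @param x A `panel_evaluation`.
#' @param ... Unused.
#' @return The metrics tibble (one row per classifier).
#' @method tidy panel_evaluation
#' @export
tidy.panel_evaluation <- function(x, ...) x$metrics

#' @rdname tidy.panel_evaluation
#' @method glance panel_evaluation
#' @export
glance.panel_evaluation <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  tibble::tibble(n_classifiers = nrow(x$metrics),
                 best_classifier = best$classifier,
                 best_accuracy = best$accuracy,
                 mean_accuracy = mean(x$metrics$accuracy))
}

#' Bar chart of panel accuracies
#'
#' @param object A `panel_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot panel_evaluation
#' @export
autoplot.panel_evaluation <- function(object, ...) {
  df <- object$metrics
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$classifier,
                                                  .data$accuracy),
                                   .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accuracy (%)",
                  title = "Classifier panel accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a saliency segmentation result
#'
#' Shows the per-pixel saliency raster with the binary mask contour
#' implied by the threshold.
#'
#' @param object A `segmentation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot segmentation_result
#' @export
autoplot.segmentation_result <- function(object, ...) {
  r <- object$saliency_raster
  df <- tidyr::expand_grid(row = seq_len(nrow(r)), col = seq_len(ncol(r)))
  df$saliency <- r[cbind(df$row, df$col)]
  df$mask <- object$mask[cbind(df$row, df$col)] == 1L
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$saliency)) +
    ggplot2::geom_point(data = df[df$mask, ], size = 0.01, alpha = 0.15,
                        colour = "red") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "saliency",
                  title = sprintf("Saliency map (threshold %.3f)",
                                  object$threshold)) +
    ggplot2::theme_void()
}

#' Heatmap of a confusion matrix
#'
#' @param cm A confusion matrix (rows = truth).
#' @return A ggplot.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(as.matrix(cm)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
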