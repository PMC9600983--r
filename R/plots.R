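#' Plot a confidence series with an optional fitted boundary
#'
#' @param object A `confidence_series`.
#' @param fit Optional [fit_step_function()] result drawn as a vertical
#'   line and its implied step.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confidence_series <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$slice_index,
                                        y = .data$confidence)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "slice index (superior → inferior)",
                  y = "below-boundary confidence (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    step_df <- tibble(
      slice_index = df$slice_index,
      level = ifelse(df$slice_index >= fit$boundary_index, 100, 0)
    )
    p <- p +
      ggplot2::geom_step(data = step_df,
                         ggplot2::aes(y = .data$level),
                         colour = "firebrick") +
      ggplot2::geom_vline(xintercept = fit$boundary_index - 0.5,
                          linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot the per-breakpoint SSE profile of a step fit
#'
#' @param object A `boundary_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boundary_fit <- function(object, ...) {
  df <- object$candidate_sse
  ggplot2::ggplot(df, ggplot2::aes(x = .data$boundary_index,
                                   y = .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$boundary_index,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "candidate boundary slice", y = "step-fit SSE") +
    ggplot2::theme_minimal()
}

#' Display a slice with an optional mask overlay
#'
#' @param image Intensity matrix in [0,1].
#' @param mask Optional 0/1 matrix overlaid in red.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_slice <- function(image, mask = NULL, title = NULL) {
  df <- expand.grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  df$value <- as.vector(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(mask) && sum(mask) > 0) {
    md <- df[as.vector(mask) == 1, ]
    p <- p + ggplot2::geom_raster(data = md, fill = "red", alpha = 0.6)
  }
  if (!is.null(title)) p <- p + ggplot2::ggtitle(title)
  p
}

#' @importFrom rlang .data
NULL
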