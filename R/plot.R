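# ggplot2 visualizations of the result objects.

#' Plot a row-detection result
#'
#' Kernel points in their original coordinates, coloured by detected row;
#' partial rows are drawn as triangles and outliers as grey crosses.
#'
#' @param object A `row_detection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot row_detection
#' @export
autoplot.row_detection <- function(object, ...) {
  pts <- object$points
  pts$what <- dplyr::case_when(
    pts$outlier ~ "outlier",
    pts$partial ~ "partial row",
    TRUE ~ "complete row"
  )
  pts$row_f <- factor(pts$row)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      data = pts[pts$what != "outlier", ],
      ggplot2::aes(colour = .data$row_f, shape = .data$what),
      size = 2
    ) +
    ggplot2::geom_point(
      data = pts[pts$what == "outlier", ],
      shape = 4, colour = "grey40", size = 2
    ) +
    ggplot2::scale_shape_manual(
      values = c("complete row" = 16, "partial row" = 17)
    ) +
    ggplot2::labs(colour = "row", shape = NULL,
                  title = sprintf("%d rows (%d complete + %d partial), %d kernels",
                                  object$c_star + object$c_half,
                                  object$c_star, object$c_half,
                                  nrow(pts))) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a synthetic ear with its ground-truth rows
#'
#' @param object A `synthetic_ear` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_ear
#' @export
autoplot.synthetic_ear <- function(object, ...) {
  pts <- object$points
  pts$row_f <- factor(pts$true_row)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$row_f)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "true row") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Mean silhouette against the segment sampling ratio, one curve per
#' squeeze factor.
#'
#' @param object A `sweep_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha,
                                       y = .data$mean_silhouette,
                                       colour = factor(.data$t))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "mean silhouette",
                  colour = "t") +
    ggplot2::theme_minimal()
}

#' Plot the silhouette profile of the row-count selection
#'
#' @param report A `silhouette_report` from [select_row_count()], or a
#'   `row_detection` object.
#' @return A ggplot object.
#' @export
plot_silhouette_profile <- function(report) {
  if (inherits(report, "row_detection")) report <- report$silhouette
  stopifnot(inherits(report, "silhouette_report"))
  ggplot2::ggplot(report$scores, ggplot2::aes(x = .data$c,
                                              y = .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = report$c_star, linetype = 2) +
    ggplot2::labs(x = "candidate row count c", y = "mean silhouette S(c)") +
    ggplot2::theme_minimal()
}
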