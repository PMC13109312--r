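# Pose normalization: principal-axis alignment, ear extent, middle segment.

#' Align a point set along its principal axis
#'
#' Centres the points at their centroid and rotates them so that the leading
#' eigenvector of the 2x2 coordinate covariance lies along the x-axis. This
#' normalizes the pose of the ear: after alignment, `x` runs along the cob
#' axis and `y` across it. Point order is preserved and the inverse transform
#' is retained so results can always be reported in the original frame.
#'
#' @param points Tibble with columns `x`, `y` (an `id` column is added when
#'   missing).
#' @return The aligned tibble, with an `axis_frame` attribute holding
#'   `rotation_angle` (degrees, in `(-90, 90]`) and `centroid`.
#' @seealso [invert_alignment()], [axis_frame()]
#' @export
align_principal_axis <- function(points) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < 2L) {
    stop_kr("need at least 2 points to estimate the principal axis.",
            "kr_degenerate_geometry")
  }
  X <- cbind(pts$x, pts$y)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (all(abs(Xc) < 1e-12)) {
    stop_kr("all points coincide; the principal axis is undefined.",
            "kr_degenerate_geometry")
  }
  C <- crossprod(Xc) / (n - 1)
  ev <- eigen(C, symmetric = TRUE)
  v1 <- ev$vectors[, 1L]
  ang <- atan2(v1[2L], v1[1L]) * 180 / pi
  # Fix the eigenvector sign ambiguity: angle constrained to (-90, 90].
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  th <- -ang * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  Xa <- Xc %*% t(R)
  out <- pts
  out$x <- Xa[, 1L]
  out$y <- Xa[, 2L]
  attr(out, "axis_frame") <- list(
    rotation_angle = ang,
    centroid = c(x = ctr[1L], y = ctr[2L])
  )
  out
}

#' Extract the pose-normalization frame of an aligned point set
#' @param aligned A tibble returned by [align_principal_axis()].
#' @return A list with `rotation_angle` (degrees) and `centroid`.
#' @export
axis_frame <- function(aligned) {
  fr <- attr(aligned, "axis_frame")
  if (is.null(fr)) {
    stop_kr("`aligned` carries no axis frame; was it produced by align_principal_axis()?",
            "kr_bad_input")
  }
  fr
}

#' Map aligned coordinates back to the original frame
#' @param aligned Aligned tibble (or any tibble with `x`, `y`).
#' @param frame Frame from [axis_frame()]; taken from `aligned` when omitted.
#' @return Tibble with coordinates in the original frame.
#' @export
invert_alignment <- function(aligned, frame = NULL) {
  if (is.null(frame)) frame <- axis_frame(aligned)
  th <- frame$rotation_angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  X <- cbind(aligned$x, aligned$y) %*% t(R)
  out <- aligned
  out$x <- X[, 1L] + frame$centroid[["x"]]
  out$y <- X[, 2L] + frame$centroid[["y"]]
  attr(out, "axis_frame") <- NULL
  out
}

#' Axial extent of an ear
#'
#' The ear length is estimated from the extreme axial coordinates,
#' `L = x_max - x_min`.
#'
#' @param points Tibble with column `x` (aligned frame).
#' @return One-row tibble with `x_min`, `x_max`, `length`.
#' @export
ear_extent <- function(points) {
  if (nrow(points) == 0L) {
    stop_kr("cannot take the extent of an empty point set.", "kr_bad_input")
  }
  tibble(
    x_min = min(points$x),
    x_max = max(points$x),
    length = max(points$x) - min(points$x)
  )
}

#' Extract the reliable middle segment of an aligned ear
#'
#' Keeps the points whose axial coordinate lies within `alpha * L` of the ear
#' centre (closed interval of total width `2 * alpha * L`). The middle of the
#' ear typically shows a quasi-grid kernel arrangement, which makes it the
#' reliable region to seed row clustering.
#'
#' @param points Aligned tibble with columns `id`, `x`, `y`.
#' @param alpha Segment sampling ratio in `(0, 0.5]`.
#' @param extent Optional precomputed [ear_extent()]; derived when omitted.
#' @param min_points Minimum number of points required in the segment
#'   (default 0 = no check); fewer raises an insufficient-segment error.
#' @return The filtered tibble (original `id`s retained).
#' @export
extract_middle_segment <- function(points, alpha, extent = NULL,
                                   min_points = 0L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5) {
    stop_kr("`alpha` must lie in (0, 0.5].", "kr_bad_param")
  }
  pts <- as_points(points)
  if (is.null(extent)) extent <- ear_extent(pts)
  centre <- extent$x_min + extent$length / 2
  lo <- centre - alpha * extent$length
  hi <- centre + alpha * extent$length
  seg <- dplyr::filter(pts, .data$x >= lo, .data$x <= hi)
  if (nrow(seg) < min_points) {
    stop_kr(sprintf(paste0("middle segment holds %d point(s), fewer than the ",
                           "required %d; consider a larger `alpha`."),
                    nrow(seg), min_points),
            "kr_insufficient_segment")
  }
  attr(seg, "segment_bounds") <- c(lo = lo, hi = hi)
  seg
}
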