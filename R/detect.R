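# Full row-detection pipeline and the row_detection result object.

#' Detect kernel rows on a maize ear
#'
#' Runs the complete detection pipeline on a set of 2-D kernel centre
#' coordinates (the output of any kernel localizer): principal-axis pose
#' normalization, ear-length estimation, extraction of the reliable middle
#' segment, squeezed K-means clustering with the row count chosen by the
#' mean silhouette coefficient, bidirectional angular row extension with
#' position correction, and partial-row recovery on the unlabeled residue.
#'
#' The result reports rows for the camera-visible side of the ear: complete
#' rows first, then partial rows, each group ordered by mean transverse
#' position. All coordinates and ids in the result refer to the original
#' input; the aligned frame is internal.
#'
#' @param points Data frame with numeric columns `x`, `y` (one row per
#'   kernel); an `id` column is added from the row order when absent.
#' @param params Hyperparameters from [unicorn_params()].
#' @return An object of class `row_detection`: a list with
#'   \describe{
#'     \item{points}{tibble `id`, `x`, `y`, `row` (integer or NA), `partial`,
#'       `outlier`, in input order and original coordinates}
#'     \item{rows}{tibble `row`, `partial`, `n_kernels`, `mean_y` (aligned
#'       frame)}
#'     \item{c_star, c_half}{complete and partial row counts}
#'     \item{silhouette}{the [select_row_count()] report of the first stage}
#'     \item{n_halved}{halved-angle corrections applied during the search}
#'     \item{frame}{the pose-normalization frame}
#'     \item{params}{the parameters used}
#'   }
#' @examples
#' ear <- simulate_ear(seed = 7)
#' det <- detect_rows(ear$points)
#' glance(det)
#' tidy(det)
#' @export
detect_rows <- function(points, params = unicorn_params()) {
  stopifnot(inherits(params, "unicorn_params"))
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < params$c_min + 1L) {
    stop_kr(sprintf("row detection needs more than c_min = %d points, got %d.",
                    params$c_min, n),
            "kr_insufficient_points")
  }

  aligned <- align_principal_axis(pts)
  extent <- ear_extent(aligned)
  segment <- extract_middle_segment(aligned, params$alpha, extent,
                                    min_points = params$c_min + 1L)
  bounds <- attr(segment, "segment_bounds")

  squeezed <- squeeze_points(segment, params$t)
  report <- select_row_count(squeezed,
                             c_min = params$c_min, c_max = params$c_max,
                             rng_seed = params$rng_seed,
                             restarts = params$kmeans_restarts)
  labels <- transfer_labels(aligned, segment, report$labels)

  searched <- bidirectional_search(aligned, labels, bounds, params$theta_T)
  labels <- searched$labels

  residue_idx <- which(is.na(labels))
  rec <- recover_partial_rows(
    aligned, residue_idx, params$t,
    rng_seed = derive_seed(params$rng_seed, 104729L),
    restarts = params$kmeans_restarts,
    min_split_silhouette = params$partial_split_min_silhouette,
    x_centre = extent$x_min + extent$length / 2
  )

  c_star <- length(unique(labels[!is.na(labels)]))
  c_half <- rec$n_partial

  # Final labels: complete rows then partial rows, each ordered by mean
  # transverse position in the aligned frame.
  partial_labels <- rep(NA_integer_, n)
  partial_labels[residue_idx] <- rec$assignment
  final <- rep(NA_integer_, n)
  complete_ids <- sort(unique(labels[!is.na(labels)]))
  mean_y <- vapply(complete_ids,
                   function(k) mean(aligned$y[which(labels == k)]), 0)
  complete_order <- complete_ids[order(mean_y)]
  for (i in seq_along(complete_order)) {
    final[which(labels == complete_order[i])] <- i
  }
  partial_flag <- rep(FALSE, n)
  if (c_half > 0L) {
    part_ids <- seq_len(c_half)
    pmean_y <- vapply(part_ids,
                      function(k) mean(aligned$y[which(partial_labels == k)]), 0)
    part_order <- part_ids[order(pmean_y)]
    for (i in seq_along(part_order)) {
      sel <- which(partial_labels == part_order[i])
      final[sel] <- c_star + i
      partial_flag[sel] <- TRUE
    }
  }

  out_points <- pts
  out_points$row <- final
  out_points$partial <- partial_flag
  out_points$outlier <- is.na(final)

  rows <- tibble(
    row = seq_len(c_star + c_half),
    partial = c(rep(FALSE, c_star), rep(TRUE, c_half))
  )
  rows$n_kernels <- vapply(rows$row,
                           function(k) sum(!is.na(final) & final == k), 0L)
  rows$mean_y <- vapply(rows$row,
                        function(k) mean(aligned$y[which(final == k)]), 0)

  structure(
    list(
      points = out_points,
      rows = rows,
      c_star = c_star,
      c_half = c_half,
      silhouette = report,
      n_halved = searched$n_halved,
      frame = axis_frame(aligned),
      params = params
    ),
    class = "row_detection"
  )
}

#' Phenotype traits of a detection result
#'
#' @param result A `row_detection` object.
#' @return One-row tibble with `kernels_per_ear` (all input kernels),
#'   `rows_per_ear` (complete + partial rows, visible side), `n_outliers`,
#'   and `kernels_per_row` as a list-column of per-row counts (complete rows
#'   first, then partial, each ordered by mean transverse position).
#' @export
ear_phenotype <- function(result) {
  stopifnot(inherits(result, "row_detection"))
  tibble(
    kernels_per_ear = nrow(result$points),
    rows_per_ear = result$c_star + result$c_half,
    n_outliers = sum(result$points$outlier),
    kernels_per_row = list(result$rows$n_kernels)
  )
}

#' @export
print.row_detection <- function(x, ...) {
  ph <- ear_phenotype(x)
  cat("<row_detection>\n")
  cat(sprintf("  kernels per ear: %d\n", ph$kernels_per_ear))
  cat(sprintf("  rows per ear (visible side): %d  (%d complete + %d partial)\n",
              ph$rows_per_ear, x$c_star, x$c_half))
  cat(sprintf("  kernels per row: %s\n",
              paste(x$rows$n_kernels, collapse = ", ")))
  cat(sprintf("  outliers: %d | halved-angle corrections: %d\n",
              ph$n_outliers, x$n_halved))
  invisible(x)
}

#' Tidy the per-row table of a detection result
#'
#' @param x A `row_detection` object.
#' @param ... Unused.
#' @return Tibble with one row per detected kernel row: `row`, `partial`,
#'   `n_kernels`, `mean_y`.
#' @method tidy row_detection
#' @export
tidy.row_detection <- function(x, ...) {
  x$rows
}

#' One-row summary of a detection result
#'
#' @param x A `row_detection` object.
#' @param ... Unused.
#' @return One-row tibble with the phenotype traits, the silhouette of the
#'   selected clustering and bookkeeping counts.
#' @method glance row_detection
#' @export
glance.row_detection <- function(x, ...) {
  ph <- ear_phenotype(x)
  best <- x$silhouette$scores$silhouette[match(x$c_star, x$silhouette$scores$c)]
  tibble(
    kernels_per_ear = ph$kernels_per_ear,
    rows_per_ear = ph$rows_per_ear,
    c_star = x$c_star,
    c_half = x$c_half,
    n_outliers = ph$n_outliers,
    n_halved = x$n_halved,
    mean_silhouette = best
  )
}
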