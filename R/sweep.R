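# Hyperparameter sensitivity sweep over the squeeze factor t and the
# segment sampling ratio alpha.

#' Sensitivity sweep of the squeeze factor and segment sampling ratio
#'
#' For every combination of `t` and `alpha`, runs pose normalization,
#' middle-segment extraction, squeezing and silhouette-based row-count
#' selection on each ear of the battery, and records the mean over ears of
#' the per-ear best silhouette `S(c*)`. Ears whose segment is too sparse to
#' cluster at a given `alpha` are counted as failures and excluded from that
#' mean. The K-means seed stream of an ear depends only on the ear and the
#' candidate cluster count — not on `t` or `alpha` — so grid cells are
#' directly comparable.
#'
#' @param battery List of `synthetic_ear` objects (from
#'   [simulate_battery()]) or of point tibbles.
#' @param alphas Numeric vector of segment sampling ratios in `(0, 0.5]`.
#' @param ts Numeric vector of squeeze factors.
#' @param params Base parameters ([unicorn_params()]); supplies the
#'   cluster-count bounds, restarts and base seed.
#' @return An object of class `sweep_result`: a tibble with columns `t`,
#'   `alpha`, `mean_silhouette`, `n_failures`, `n_ears`.
#' @export
sweep_alpha_t <- function(battery, alphas, ts, params = unicorn_params()) {
  if (length(battery) == 0L) {
    stop_kr("`battery` must contain at least one ear.", "kr_bad_input")
  }
  if (length(alphas) == 0L || length(ts) == 0L) {
    stop_kr("`alphas` and `ts` must be non-empty.", "kr_bad_input")
  }
  pts_list <- purrr::map(battery, function(e) {
    if (inherits(e, "synthetic_ear")) e$points else as_points(e)
  })
  aligned <- purrr::map(pts_list, align_principal_axis)
  extents <- purrr::map(aligned, ear_extent)

  grid <- tidyr::expand_grid(t = ts, alpha = alphas)
  res <- purrr::pmap_dfr(grid, function(t, alpha) {
    best <- rep(NA_real_, length(aligned))
    for (i in seq_along(aligned)) {
      seg <- tryCatch(
        extract_middle_segment(aligned[[i]], alpha, extents[[i]],
                               min_points = params$c_min + 1L),
        kernelrows_error = function(e) NULL
      )
      if (is.null(seg)) next
      sq <- squeeze_points(seg, t)
      rep_i <- tryCatch(
        select_row_count(sq, c_min = params$c_min, c_max = params$c_max,
                         rng_seed = derive_seed(params$rng_seed, i),
                         restarts = params$kmeans_restarts),
        kernelrows_error = function(e) NULL
      )
      if (is.null(rep_i)) next
      best[i] <- max(rep_i$scores$silhouette, na.rm = TRUE)
    }
    tibble(
      t = t, alpha = alpha,
      mean_silhouette = mean(best, na.rm = TRUE),
      n_failures = sum(is.na(best)),
      n_ears = length(aligned)
    )
  })
  class(res) <- c("sweep_result", class(res))
  res
}

#' Write a sweep result as a delimited table
#' @param sweep A `sweep_result` tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, delim = ",") {
  readr::write_delim(
    dplyr::select(sweep, "t", "alpha", "mean_silhouette", "n_failures"),
    path, delim = delim
  )
  invisible(path)
}
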