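#' Detection hyperparameters
#'
#' Bundles and validates the hyperparameters of the row-detection pipeline.
#' The defaults (`t = 1000`, `alpha = 0.09`, `theta_T = 10`) are the values
#' selected by sensitivity analysis of the squeezed-clustering stage; see
#' `vignette("kernel-row-detection")` for what each controls and why.
#'
#' @param t Squeeze factor (dimensionless, > 0). Axial (`x`) coordinates of
#'   the middle segment are divided by `t` before K-means so that each row
#'   collapses towards a single transverse band; the `x` contribution to the
#'   Euclidean distance scales as `1/t^2`.
#' @param alpha Segment sampling ratio in `(0, 0.5]`. The clustered middle
#'   segment covers axial positions within `alpha * L` of the ear centre
#'   (total width `2 * alpha * L` for ear length `L`).
#' @param theta_T Base angle threshold in degrees (> 0) of the bidirectional
#'   row search. Candidate angles `<= theta_T` are accepted as-is, angles in
#'   `(theta_T, 2 * theta_T]` are accepted with a halved-angle direction
#'   update, larger angles are rejected as outliers.
#' @param c_min,c_max Search bounds for the number of visible rows evaluated
#'   by the mean silhouette criterion (defaults 2 and 10, the plausible range
#'   for the camera-facing side of an ear).
#' @param rng_seed Integer seed making K-means restarts reproducible.
#' @param kmeans_restarts Number of independent k-means++ initializations per
#'   candidate cluster count (>= 1); the best fit by total within-cluster sum
#'   of squares is kept.
#' @param partial_split_min_silhouette Minimum mean silhouette of the 2-means
#'   split of the unlabeled residue required to declare two partial rows
#'   rather than one. Set to 0 to accept any positive-silhouette split.
#'
#' @return A named list of class `unicorn_params`.
#' @examples
#' unicorn_params()
#' unicorn_params(t = 300, rng_seed = 42)
#' @export
unicorn_params <- function(t = 1000,
                           alpha = 0.09,
                           theta_T = 10,
                           c_min = 2L,
                           c_max = 10L,
                           rng_seed = 1L,
                           kmeans_restarts = 10L,
                           partial_split_min_silhouette = 0.75) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    stop_kr("`t` must be a single positive number.", "kr_bad_param")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 0.5) {
    stop_kr("`alpha` must lie in (0, 0.5].", "kr_bad_param")
  }
  if (!is.numeric(theta_T) || length(theta_T) != 1L || !is.finite(theta_T) ||
      theta_T <= 0) {
    stop_kr("`theta_T` must be a single positive angle in degrees.",
            "kr_bad_param")
  }
  c_min <- as.integer(c_min)
  c_max <- as.integer(c_max)
  if (is.na(c_min) || c_min < 2L) {
    stop_kr("`c_min` must be an integer >= 2.", "kr_bad_param")
  }
  if (is.na(c_max) || c_max < c_min) {
    stop_kr("`c_max` must be an integer >= `c_min`.", "kr_bad_param")
  }
  rng_seed <- as.integer(rng_seed)
  if (is.na(rng_seed)) stop_kr("`rng_seed` must be an integer.", "kr_bad_param")
  kmeans_restarts <- as.integer(kmeans_restarts)
  if (is.na(kmeans_restarts) || kmeans_restarts < 1L) {
    stop_kr("`kmeans_restarts` must be an integer >= 1.", "kr_bad_param")
  }
  if (!is.numeric(partial_split_min_silhouette) ||
      length(partial_split_min_silhouette) != 1L ||
      !is.finite(partial_split_min_silhouette) ||
      partial_split_min_silhouette < 0 || partial_split_min_silhouette >= 1) {
    stop_kr("`partial_split_min_silhouette` must lie in [0, 1).",
            "kr_bad_param")
  }
  structure(
    list(
      t = t, alpha = alpha, theta_T = theta_T,
      c_min = c_min, c_max = c_max,
      rng_seed = rng_seed, kmeans_restarts = kmeans_restarts,
      partial_split_min_silhouette = partial_split_min_silhouette
    ),
    class = "unicorn_params"
  )
}

#' @export
print.unicorn_params <- function(x, ...) {
  cat("<unicorn_params>\n")
  cat(sprintf("  t = %g, alpha = %g, theta_T = %g deg\n",
              x$t, x$alpha, x$theta_T))
  cat(sprintf("  row-count search: %d..%d | seed %d, %d k-means restarts\n",
              x$c_min, x$c_max, x$rng_seed, x$kmeans_restarts))
  invisible(x)
}

#' Load detection parameters from a JSON file and/or overrides
#'
#' Reads a flat JSON object of parameter fields (any subset of the arguments
#' of [unicorn_params()]), applies `...` overrides on top, and validates.
#'
#' @param path Optional path to a JSON parameter file.
#' @param ... Named overrides applied after the file values.
#' @return A validated `unicorn_params` object.
#' @export
load_params <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(unicorn_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop_kr(paste0("unknown parameter field(s): ",
                   paste(unknown, collapse = ", ")), "kr_bad_param")
  }
  do.call(unicorn_params, vals)
}

#' Write detection parameters to a JSON file
#'
#' @param params A `unicorn_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "unicorn_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
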