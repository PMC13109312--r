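# Synthetic ear generator: cylinder-projection point layouts with ground
# truth, emulating spiral and linear kernel arrangements, end taper, partial
# rows, localization jitter and missing kernels.

centered_azimuth <- function(az) {
  ((az + 180) %% 360) - 180
}

taper_factor <- function(x, ear_length, taper_strength) {
  1 - taper_strength * (2 * x / ear_length - 1)^2
}

#' Simulate one maize ear as a 2-D kernel point layout
#'
#' Kernels grow on a cylinder of the given radius: row `j` sits at azimuth
#' `(j - 1) * 360 / total_rows`, kernel `m` of a row at axial position
#' `m * ear_length / kernels_per_row`, with the azimuth advanced by
#' `twist_rate` degrees per pixel of axial advance (0 gives the linear
#' arrangement; nonzero the spiral one, so rows drift across the silhouette
#' edge and become partial). A kernel is visible iff its centred azimuth
#' lies in `[-visible_window/2, visible_window/2)`; visible kernels are
#' projected to `(x, radius * taper(x) * sin(azimuth))` with the elliptical
#' end taper `taper(x) = 1 - taper_strength * (2 x / ear_length - 1)^2`.
#' Isotropic Gaussian jitter emulates localization error and i.i.d.
#' Bernoulli dropout emulates missing kernels. Points are emitted in
#' shuffled order and the whole layout is reproducible from `seed`.
#'
#' Ground truth: visible rows that keep at least 2 emitted kernels are
#' numbered `1..K` by mean transverse position; kernels of thinner rows
#' carry an `NA` label and are excluded from the truth phenotype.
#'
#' @param total_rows Whole-ear row count (biological prior 12-20; even
#'   values give `total_rows / 2` visible rows under the default window).
#' @param kernels_per_row Kernels per complete row.
#' @param ear_length Ear length in pixels.
#' @param radius Cylinder radius in pixels.
#' @param twist_rate Azimuth advance in degrees per pixel of axial advance.
#' @param taper_strength End taper in `[0, 1)`; 0 disables tapering.
#' @param jitter_sigma Standard deviation (pixels) of the isotropic
#'   localization jitter.
#' @param p_miss Per-kernel dropout probability in `[0, 1]`.
#' @param visible_window Full width (degrees) of the visible azimuth
#'   window; the default 180 shows half the cylinder, as a camera does.
#' @param seed Integer seed.
#' @return An object of class `synthetic_ear`: a list with `points`
#'   (tibble `id`, `x`, `y`, `true_row`), `phenotype` (one-row tibble with
#'   `kernels_per_ear`, `rows_per_ear` and list-column `kernels_per_row`),
#'   `config` and `seed`.
#' @examples
#' ear <- simulate_ear(total_rows = 12, seed = 1)
#' ear$phenotype
#' @export
simulate_ear <- function(total_rows = 14L,
                         kernels_per_row = 20L,
                         ear_length = 800,
                         radius = 100,
                         twist_rate = 0.02,
                         taper_strength = 0.3,
                         jitter_sigma = 1,
                         p_miss = 0,
                         visible_window = 180,
                         seed = 1L) {
  total_rows <- as.integer(total_rows)
  kernels_per_row <- as.integer(kernels_per_row)
  if (is.na(total_rows) || total_rows < 1L) {
    stop_kr("`total_rows` must be a positive integer.", "kr_bad_param")
  }
  if (is.na(kernels_per_row) || kernels_per_row < 1L) {
    stop_kr("`kernels_per_row` must be a positive integer.", "kr_bad_param")
  }
  if (ear_length <= 0 || radius <= 0) {
    stop_kr("`ear_length` and `radius` must be positive.", "kr_bad_param")
  }
  if (taper_strength < 0 || taper_strength >= 1) {
    stop_kr("`taper_strength` must lie in [0, 1).", "kr_bad_param")
  }
  if (jitter_sigma < 0) stop_kr("`jitter_sigma` must be >= 0.", "kr_bad_param")
  if (p_miss < 0 || p_miss > 1) {
    stop_kr("`p_miss` must lie in [0, 1].", "kr_bad_param")
  }
  if (visible_window <= 0 || visible_window > 360) {
    stop_kr("`visible_window` must lie in (0, 360].", "kr_bad_param")
  }

  config <- list(
    total_rows = total_rows, kernels_per_row = kernels_per_row,
    ear_length = ear_length, radius = radius, twist_rate = twist_rate,
    taper_strength = taper_strength, jitter_sigma = jitter_sigma,
    p_miss = p_miss, visible_window = visible_window
  )

  grid <- tidyr::expand_grid(
    row = seq_len(total_rows),
    m = seq_len(kernels_per_row)
  )
  grid$x0 <- grid$m * (ear_length / kernels_per_row)
  phi <- (grid$row - 1) * (360 / total_rows)
  az <- centered_azimuth(phi + twist_rate * grid$x0)
  grid$visible <- az >= -visible_window / 2 & az < visible_window / 2
  grid$y0 <- radius * taper_factor(grid$x0, ear_length, taper_strength) *
    sin(az * pi / 180)

  N <- nrow(grid)
  set.seed(seed)
  jit_x <- stats::rnorm(N, 0, jitter_sigma)
  jit_y <- stats::rnorm(N, 0, jitter_sigma)
  dropped <- stats::runif(N) < p_miss
  keep <- grid$visible & !dropped
  shuffle <- sample.int(sum(keep))

  kept <- grid[keep, , drop = FALSE]
  kept$x <- kept$x0 + jit_x[keep]
  kept$y <- kept$y0 + jit_y[keep]
  kept <- kept[shuffle, , drop = FALSE]

  # truth labels: visible rows with >= 2 emitted kernels, ordered by mean y
  counts <- table(kept$row)
  valid_rows <- as.integer(names(counts)[counts >= 2L])
  row_my <- vapply(valid_rows, function(r) mean(kept$y[kept$row == r]), 0)
  valid_rows <- valid_rows[order(row_my)]
  true_row <- match(kept$row, valid_rows)

  points <- tibble(
    id = seq_len(nrow(kept)),
    x = kept$x,
    y = kept$y,
    true_row = as.integer(true_row)
  )
  kpr <- if (length(valid_rows) > 0L) {
    vapply(seq_along(valid_rows), function(k) sum(!is.na(true_row) & true_row == k), 0L)
  } else {
    integer()
  }
  phenotype <- tibble(
    kernels_per_ear = nrow(points),
    rows_per_ear = length(valid_rows),
    kernels_per_row = list(kpr)
  )
  structure(
    list(points = points, phenotype = phenotype, config = config, seed = seed),
    class = "synthetic_ear"
  )
}

#' @export
print.synthetic_ear <- function(x, ...) {
  cat("<synthetic_ear>\n")
  cat(sprintf("  %d kernels, %d visible rows (of %d whole-ear), seed %d\n",
              x$phenotype$kernels_per_ear, x$phenotype$rows_per_ear,
              x$config$total_rows, x$seed))
  cat(sprintf("  twist %.3f deg/px, taper %.2f, jitter %.2f px, p_miss %.2f\n",
              x$config$twist_rate, x$config$taper_strength,
              x$config$jitter_sigma, x$config$p_miss))
  invisible(x)
}

# Minimum transverse gap between adjacent visible rows at the ear centre;
# used to express jitter as a fraction of the row spacing.
min_row_gap <- function(total_rows, radius, twist_rate, ear_length,
                        visible_window = 180) {
  phi <- (seq_len(total_rows) - 1) * (360 / total_rows)
  az <- centered_azimuth(phi + twist_rate * ear_length / 2)
  az <- az[az >= -visible_window / 2 & az < visible_window / 2]
  if (length(az) < 2L) return(2 * radius)
  min(diff(sort(radius * sin(az * pi / 180))))
}

#' Simulate a battery of ears with per-ear sampled configurations
#'
#' Generates `n_ears` reproducible ears, sampling each configuration field
#' uniformly from its stated range: discrete fields (`total_rows`,
#' `kernels_per_row`) from the given set / integer range, `twist_rate` from
#' a continuous interval. A scalar (or min = max) fixes the field. Jitter
#' can be tied to the row spacing via `jitter_frac`: the jitter standard
#' deviation becomes that fraction of the minimum transverse gap between
#' adjacent visible rows at the ear centre.
#'
#' The defaults are the battery conditions used throughout the package's
#' validation: visible rows 5..8, 15-25 kernels per row, linear to
#' moderately spiral arrangements and localization jitter at 5% of the
#' tightest row gap. See `vignette("kernel-row-detection")`.
#'
#' @param n_ears Number of ears.
#' @param seed Integer seed; ear `i` uses a seed derived from `(seed, i)`.
#' @param total_rows Set of whole-ear row counts to sample from.
#' @param kernels_per_row Integer range `c(min, max)` (or a set) of kernels
#'   per row.
#' @param twist_rate Interval `c(min, max)` of the twist rate (deg/px).
#' @param taper_strength,p_miss,ear_length,radius,visible_window Fixed
#'   configuration fields (scalars).
#' @param jitter_frac Jitter as a fraction of the minimum centre row gap;
#'   ignored when `jitter_sigma` is given.
#' @param jitter_sigma Absolute jitter standard deviation in pixels
#'   (overrides `jitter_frac`).
#' @return A list of `synthetic_ear` objects.
#' @export
simulate_battery <- function(n_ears = 50L,
                             seed = 1L,
                             total_rows = c(10L, 12L, 14L, 16L),
                             kernels_per_row = c(15L, 25L),
                             twist_rate = c(0, 0.025),
                             taper_strength = 0.3,
                             p_miss = 0,
                             ear_length = 800,
                             radius = 100,
                             visible_window = 180,
                             jitter_frac = 0.05,
                             jitter_sigma = NULL) {
  n_ears <- as.integer(n_ears)
  if (is.na(n_ears) || n_ears < 1L) {
    stop_kr("`n_ears` must be a positive integer.", "kr_bad_param")
  }
  if (length(total_rows) < 1L || length(kernels_per_row) < 1L ||
      length(twist_rate) < 1L) {
    stop_kr("configuration ranges must be non-empty.", "kr_bad_param")
  }
  kpr_set <- if (length(kernels_per_row) == 2L) {
    seq(min(kernels_per_row), max(kernels_per_row))
  } else {
    kernels_per_row
  }
  purrr::map(seq_len(n_ears), function(i) {
    set.seed(derive_seed(seed, i, 1L))
    tr <- if (length(total_rows) == 1L) total_rows else sample(total_rows, 1L)
    kpr <- if (length(kpr_set) == 1L) kpr_set else sample(kpr_set, 1L)
    tw <- if (length(twist_rate) == 1L) {
      twist_rate
    } else {
      stats::runif(1L, min(twist_rate), max(twist_rate))
    }
    js <- if (!is.null(jitter_sigma)) {
      jitter_sigma
    } else {
      jitter_frac * min_row_gap(tr, radius, tw, ear_length, visible_window)
    }
    simulate_ear(
      total_rows = tr, kernels_per_row = kpr, ear_length = ear_length,
      radius = radius, twist_rate = tw, taper_strength = taper_strength,
      jitter_sigma = js, p_miss = p_miss, visible_window = visible_window,
      seed = derive_seed(seed, i, 2L)
    )
  })
}
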