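# Shared internal helpers: deterministic seed streams and seeded K-means.

# Mix an integer base seed with extra integer keys into a new seed in
# [1, 2^31 - 2]. A plain multiplicative hash is enough here: it only has to
# decorrelate the RNG streams of sub-computations, not be cryptographic.
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  acc <- 0
  for (k in keys) {
    acc <- (acc * 48271 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(acc %% 2147483645) + 1L
}

# Squared Euclidean distances from every row of X to a single point p.
row_dist2 <- function(X, p) {
  (X[, 1L] - p[1L])^2 + (X[, 2L] - p[2L])^2
}

# k-means++ seeding: returns k row indices of X. Assumes the RNG state is set
# by the caller. Falls back to uniform sampling when all remaining points
# coincide with a chosen centre.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- row_dist2(X, X[centers[1L], ])
  if (k > 1L) {
    for (j in 2L:k) {
      if (all(d2 <= 0)) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, row_dist2(X, X[centers[j], ]))
    }
  }
  centers
}

# Seeded K-means with `restarts` independent k-means++ initializations,
# keeping the fit with the lowest total within-cluster sum of squares.
# Returns a stats::kmeans object, or NULL when no restart produced a valid
# fit (e.g. fewer than k distinct points).
fit_kmeans <- function(X, k, seed, restarts = 10L) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- X[kmeanspp_init(X, k), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = init, iter.max = 100L)),
      error = function(e) NULL
    )
    if (is.null(km)) next
    # Relative tolerance keeps the earliest restart among numerical ties, so
    # the chosen partition is stable under isometries of the input.
    if (is.null(best) ||
        km$tot.withinss < best$tot.withinss * (1 - 1e-9) - 1e-12) {
      best <- km
    }
  }
  best
}

stop_kr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "kernelrows_error"))
}

# Validate a point table: needs numeric, finite x and y; adds an `id` column
# (original order) when absent.
as_points <- function(points) {
  if (!is.data.frame(points)) {
    stop_kr("`points` must be a data frame with columns `x` and `y`.",
            "kr_bad_input")
  }
  if (!all(c("x", "y") %in% names(points))) {
    stop_kr("`points` must have columns `x` and `y`.", "kr_bad_input")
  }
  pts <- tibble::as_tibble(points)
  if (!is.numeric(pts$x) || !is.numeric(pts$y) ||
      !all(is.finite(pts$x)) || !all(is.finite(pts$y))) {
    stop_kr("`x` and `y` must be finite numeric coordinates.", "kr_bad_input")
  }
  if (!"id" %in% names(pts)) {
    pts <- dplyr::mutate(pts, id = dplyr::row_number(), .before = 1L)
  }
  if (anyDuplicated(pts$id)) {
    stop_kr("point `id` values must be unique.", "kr_bad_input")
  }
  pts
}
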