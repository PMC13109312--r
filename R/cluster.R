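# Squeezed clustering: axial compression, silhouette scoring, and row-count
# selection by the mean silhouette coefficient.

#' Squeeze the axial coordinates of a point set
#'
#' Divides `x` by the squeeze factor `t`, leaving `y` untouched, so that the
#' points of one kernel row collapse towards a single transverse band before
#' K-means. The contribution of `x` to squared Euclidean distances then
#' scales as `1/t^2` and vanishes in the large-`t` limit.
#'
#' @param points Tibble with columns `x`, `y`.
#' @param t Squeeze factor (> 0).
#' @return The tibble with `x` divided by `t`; the factor is kept in the
#'   `squeeze_t` attribute.
#' @export
squeeze_points <- function(points, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    stop_kr("`t` must be a single positive number.", "kr_bad_param")
  }
  out <- tibble::as_tibble(points)
  out$x <- out$x / t
  attr(out, "squeeze_t") <- t
  out
}

#' Silhouette scores of a clustered point set
#'
#' For point i with mean intra-cluster distance `a(i)` (over the other
#' members of its own cluster) and `b(i)` the smallest mean distance to any
#' other cluster, the silhouette is `s(i) = (b(i) - a(i)) / max(a(i), b(i))`.
#' Distances are Euclidean. Points in singleton clusters score 0 by
#' convention (their `a(i)` is undefined).
#'
#' @param points Tibble with columns `x`, `y` (typically squeezed).
#' @param labels Cluster labels, one per point, at least two distinct values.
#' @return Tibble with columns `id` (when present in `points`), `cluster`
#'   and `silhouette`; its mean silhouette is attached as the
#'   `mean_silhouette` attribute.
#' @export
silhouette_scores <- function(points, labels) {
  n <- nrow(points)
  if (length(labels) != n) {
    stop_kr("`labels` must have one entry per point.", "kr_bad_input")
  }
  if (anyNA(labels)) stop_kr("`labels` must not contain NA.", "kr_bad_input")
  f <- factor(labels)
  k <- nlevels(f)
  if (k < 2L) {
    stop_kr("silhouette is undefined for a single cluster.",
            "kr_undefined_silhouette")
  }
  g <- as.integer(f)
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  sums <- rowsum(D, g)                      # k x n: summed distance to each cluster
  sizes <- tabulate(g, nbins = k)
  own_sum <- sums[cbind(g, seq_len(n))]
  a <- own_sum / (sizes[g] - 1)
  means <- sums / sizes
  means[cbind(g, seq_len(n))] <- Inf        # exclude own cluster from b(i)
  b <- apply(means, 2L, min)
  s <- unname((b - a) / pmax(a, b))
  s[!is.finite(s)] <- 0                     # duplicate-point degeneracies
  s[sizes[g] == 1L] <- 0                    # singleton convention
  out <- tibble(cluster = as.vector(labels), silhouette = s)
  if ("id" %in% names(points)) out <- dplyr::bind_cols(tibble(id = points$id), out)
  attr(out, "mean_silhouette") <- mean(s)
  out
}

#' Mean silhouette of a clustering
#' @inheritParams silhouette_scores
#' @return The mean silhouette coefficient, a number in `[-1, 1]`.
#' @export
mean_silhouette <- function(points, labels) {
  attr(silhouette_scores(points, labels), "mean_silhouette")
}

#' Select the number of rows by the mean silhouette criterion
#'
#' Fits seeded K-means for every candidate cluster count `c` in
#' `[c_min, min(c_max, n - 1)]` (k-means++ initialization, `restarts`
#' independent starts, best within-cluster sum of squares kept) and selects
#' `c* = argmax S(c)`, the count with the largest mean silhouette. Ties are
#' broken towards the smallest `c`. Candidate counts where K-means cannot
#' produce two or more non-empty clusters score `NA` and are skipped.
#'
#' @param points Tibble with columns `x`, `y` (typically squeezed).
#' @param c_min,c_max Cluster-count search bounds.
#' @param rng_seed Integer seed; each candidate count gets a derived stream,
#'   so results are reproducible and independent of evaluation order.
#' @param restarts K-means restarts per candidate count.
#' @return An object of class `silhouette_report`: a list with
#'   `scores` (tibble of `c`, `silhouette`), `c_star`, `labels` (fitted
#'   cluster labels at `c_star`, values `1..c_star`) and `per_point`
#'   (silhouette tibble at `c_star`).
#' @export
select_row_count <- function(points, c_min = 2L, c_max = 10L,
                             rng_seed = 1L, restarts = 10L) {
  n <- nrow(points)
  c_min <- as.integer(c_min)
  if (n <= c_min) {
    stop_kr(sprintf("need more than c_min = %d points, got %d.", c_min, n),
            "kr_insufficient_points")
  }
  c_hi <- min(as.integer(c_max), n - 1L)
  X <- cbind(points$x, points$y)
  cands <- c_min:c_hi
  all_labels <- vector("list", length(cands))
  S <- rep(NA_real_, length(cands))
  for (i in seq_along(cands)) {
    km <- fit_kmeans(X, cands[i], derive_seed(rng_seed, cands[i]), restarts)
    if (is.null(km)) next
    lab <- km$cluster
    if (length(unique(lab)) < 2L) next
    all_labels[[i]] <- lab
    S[i] <- mean_silhouette(points, lab)
  }
  if (all(is.na(S))) {
    stop_kr("no candidate cluster count produced a valid clustering.",
            "kr_insufficient_points")
  }
  best <- which(S == max(S, na.rm = TRUE))[1L]  # smallest c wins ties
  labels <- as.integer(factor(all_labels[[best]]))
  structure(
    list(
      scores = tibble(c = cands, silhouette = S),
      c_star = length(unique(labels)),
      labels = labels,
      per_point = silhouette_scores(points, all_labels[[best]])
    ),
    class = "silhouette_report"
  )
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat("<silhouette_report>\n")
  cat(sprintf("  c* = %d (mean silhouette %.4f)\n", x$c_star,
              x$scores$silhouette[match(x$c_star, x$scores$c)]))
  print(x$scores)
  invisible(x)
}

#' Transfer middle-segment cluster labels to the full point set
#'
#' @param points Full point tibble with an `id` column.
#' @param segment Middle-segment tibble (subset of `points`, same ids).
#' @param labels Cluster labels aligned to `segment` rows.
#' @return Integer vector of length `nrow(points)`: row labels `1..c*` for
#'   segment members, `NA` (unassigned) elsewhere.
#' @export
transfer_labels <- function(points, segment, labels) {
  if (nrow(segment) != length(labels)) {
    stop_kr("`labels` must align with `segment` rows.", "kr_internal")
  }
  pos <- match(segment$id, points$id)
  if (anyNA(pos)) {
    stop_kr("segment ids not found in the full point set.", "kr_internal")
  }
  out <- rep(NA_integer_, nrow(points))
  out[pos] <- as.integer(factor(labels))
  out
}
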