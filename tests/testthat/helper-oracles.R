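# Independent oracles and small fixture builders used across the suite.

# Brute-force silhouette: plain per-point loops over the definition
# s(i) = (b(i) - a(i)) / max(a(i), b(i)), a(i) the mean distance to the other
# members of i's cluster, b(i) the smallest mean distance to another cluster.
# Deliberately naive and independent of the package implementation.
brute_silhouette <- function(x, y, labels) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    same <- which(labels == labels[i])
    same <- same[same != i]
    if (length(same) == 0L) {
      s[i] <- 0
      next
    }
    a <- mean(d[same])
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[labels == k]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# Exhaustive maximum-overlap one-to-one matching value on a contingency
# matrix: tries every injective assignment of the smaller side.
exhaustive_match_value <- function(C) {
  if (ncol(C) > nrow(C)) C <- t(C)
  nc <- ncol(C)
  best <- 0
  rows_avail <- seq_len(nrow(C))
  recurse <- function(j, used, acc) {
    if (j > nc) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(j + 1L, used, acc) # leave column j unmatched
    for (i in setdiff(rows_avail, used)) {
      recurse(j + 1L, c(used, i), acc + C[i, j])
    }
  }
  recurse(1L, integer(0), 0)
  best
}

# Horizontal band fixture: `k` rows at the given y levels, `per` points each,
# x spread uniformly on [0, span].
make_bands <- function(y_levels, per = 5L, span = 20, jitter = 0, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    x = rep(seq(0, span, length.out = per), times = length(y_levels)),
    y = rep(y_levels, each = per) + stats::rnorm(per * length(y_levels), 0, jitter),
    band = rep(seq_along(y_levels), each = per)
  )
}

rotate_points <- function(points, degrees) {
  th <- degrees * pi / 180
  out <- points
  out$x <- cos(th) * points$x - sin(th) * points$y
  out$y <- sin(th) * points$x + cos(th) * points$y
  out
}
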