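# Squeezing, silhouette scoring and row-count selection.

test_that("squeezing divides x by t and leaves y untouched", {
  pts <- tibble::tibble(x = c(2000, -500), y = c(5, 7))
  sq <- squeeze_points(pts, 1000)
  expect_equal(sq$x, c(2, -0.5))
  expect_equal(sq$y, pts$y)
  expect_equal(squeeze_points(pts, 1)$x, pts$x)
  expect_error(squeeze_points(pts, 0), class = "kr_bad_param")
  expect_error(squeeze_points(pts, -2), class = "kr_bad_param")
})

test_that("silhouette matches the closed-form two-cluster example", {
  pts <- tibble::tibble(x = c(0, 0, 10, 10), y = c(0, 1, 0, 1))
  s <- silhouette_scores(pts, c(1, 1, 2, 2))
  b <- (10 + sqrt(101)) / 2
  expect_equal(s$silhouette[1], (b - 1) / b, tolerance = 1e-12)
  expect_equal(s$silhouette, s$silhouette[c(1, 1, 1, 1)]) # symmetric layout
  expect_error(silhouette_scores(pts, rep(1, 4)),
               class = "kr_undefined_silhouette")
})

test_that("silhouette handles singletons, ties and stays within [-1, 1]", {
  # a(i) = b(i) forces s(i) = 0: equilateral-like symmetric configuration
  pts <- tibble::tibble(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2))
  s <- silhouette_scores(pts, c(1, 1, 2))
  expect_equal(s$silhouette[3], 0) # singleton convention
  expect_equal(s$silhouette[1], 0) # all pairwise distances equal: a = b

  set.seed(7)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    pts <- tibble::tibble(x = rnorm(n), y = rnorm(n))
    lab <- sample(1:4, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s <- silhouette_scores(pts, lab)$silhouette
    expect_true(all(s >= -1 - 1e-12 & s <= 1 + 1e-12))
  }
})

test_that("silhouette agrees with the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    x <- rnorm(n, sd = 5)
    y <- rnorm(n, sd = 5)
    lab <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s_pkg <- silhouette_scores(tibble::tibble(x = x, y = y), lab)$silhouette
    s_ref <- brute_silhouette(x, y, lab)
    expect_lt(max(abs(s_pkg - s_ref)), 1e-10)
  }
})

test_that("row-count selection finds clear horizontal bands", {
  bands3 <- make_bands(c(0, 10, 20), per = 5, span = 2000)
  sq3 <- squeeze_points(bands3, 1000)
  rep3 <- select_row_count(sq3, rng_seed = 5)
  expect_equal(rep3$c_star, 3L)
  # recovered partition matches the bands exactly
  expect_equal(length(unique(paste(rep3$labels, bands3$band))), 3L)

  bands2 <- make_bands(c(0, 10), per = 6, span = 2000)
  rep2 <- select_row_count(squeeze_points(bands2, 1000), rng_seed = 5)
  expect_equal(rep2$c_star, 2L)

  # c_star attains the maximum of the score table, smallest c among ties
  mx <- max(rep3$scores$silhouette, na.rm = TRUE)
  expect_equal(rep3$c_star, min(rep3$scores$c[which(rep3$scores$silhouette == mx)]))
})

test_that("row-count selection is deterministic in the seed and bounded by n - 1", {
  bands <- make_bands(c(0, 8, 16, 24), per = 4, span = 1500, jitter = 0.5,
                      seed = 3)
  sq <- squeeze_points(bands, 1000)
  a <- select_row_count(sq, rng_seed = 123)
  b <- select_row_count(sq, rng_seed = 123)
  expect_identical(a$labels, b$labels)
  expect_identical(a$c_star, b$c_star)
  expect_true(max(a$scores$c) <= nrow(bands) - 1)
  expect_error(select_row_count(sq[1:2, ], rng_seed = 1),
               class = "kr_insufficient_points")
})

test_that("labels transfer to the full set with NA elsewhere and contiguous ids", {
  pts <- tibble::tibble(id = 1:10, x = 1:10, y = 0)
  seg <- pts[4:7, ]
  lab <- transfer_labels(pts, seg, c(2L, 2L, 5L, 5L))
  expect_equal(which(!is.na(lab)), 4:7)
  expect_setequal(unique(lab[!is.na(lab)]), c(1L, 2L)) # relabelled 1..c*
  expect_error(transfer_labels(pts, seg, c(1L, 2L)), class = "kr_internal")
})

test_that("squeezed distances shrink monotonically in t towards |dy|", {
  set.seed(9)
  pts <- tibble::tibble(x = runif(30, 0, 2000), y = runif(30, 0, 200))
  prev <- NULL
  for (t in c(10, 100, 1000, 1e6)) {
    sq <- squeeze_points(pts, t)
    d <- as.vector(dist(cbind(sq$x, sq$y)))
    if (!is.null(prev)) expect_true(all(d <= prev + 1e-12))
    prev <- d
  }
  dy <- as.vector(dist(pts$y))
  dx <- as.vector(dist(pts$x))
  expect_true(all(abs(prev - dy) <= 1e-6 * (1 + dx)))
})
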