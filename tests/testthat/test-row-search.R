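# Angular greedy search, correction regimes and partial-row recovery.

test_that("angle_between matches closed forms and rejects zero vectors", {
  expect_equal(angle_between(c(1, 0), c(1, 0)), 0)
  expect_equal(angle_between(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_between(c(1, 0), c(1, 1)), 45)
  expect_equal(angle_between(c(1, 0), c(-1, 0)), 180)
  expect_error(angle_between(c(0, 0), c(1, 0)), class = "kr_undefined_angle")
})

test_that("correction regimes follow the three angle bands", {
  v <- c(1, 0)
  deg <- function(a) c(cos(a * pi / 180), sin(a * pi / 180))

  a <- classify_and_correct(v, deg(5), theta_T = 10)
  expect_equal(a$regime, "accept")
  expect_equal(a$v_updated, deg(5), tolerance = 1e-12)

  b <- classify_and_correct(v, deg(16), theta_T = 10)
  expect_equal(b$regime, "accept_halved")
  expect_equal(b$v_updated, c(0.99027, 0.13917), tolerance = 1e-4)
  expect_equal(angle_between(v, b$v_updated), 8, tolerance = 1e-9)

  cc <- classify_and_correct(v, deg(25), theta_T = 10)
  expect_equal(cc$regime, "reject")
  expect_equal(cc$v_updated, v)
})

test_that("halved-angle updates bisect correctly for any direction and sign", {
  set.seed(21)
  for (rep in 1:50) {
    theta_T <- runif(1, 5, 20)
    base <- runif(1, 0, 360)
    th <- runif(1, theta_T + 1e-6, 2 * theta_T)
    sgn <- sample(c(-1, 1), 1)
    v <- c(cos(base * pi / 180), sin(base * pi / 180))
    vn <- c(cos((base + sgn * th) * pi / 180), sin((base + sgn * th) * pi / 180))
    out <- classify_and_correct(v, vn, theta_T)
    expect_equal(out$regime, "accept_halved")
    expect_equal(angle_between(v, out$v_updated), th / 2, tolerance = 1e-6)
    expect_equal(angle_between(vn, out$v_updated), th / 2, tolerance = 1e-6)
    expect_equal(sum(out$v_updated^2), 1, tolerance = 1e-12)
  }
})

test_that("frontiers start at extreme-x members with axial unit vectors", {
  pts <- tibble::tibble(id = 1:3, x = c(41, 50, 59), y = c(1, 2, 3))
  lab <- c(1L, 1L, 1L)
  fr_r <- kernelrows:::init_frontiers(pts, lab, +1)
  expect_equal(fr_r$boundary[1, ], c(59, 3))
  expect_equal(fr_r$v[1, ], c(1, 0))
  fr_l <- kernelrows:::init_frontiers(pts, lab, -1)
  expect_equal(fr_l$boundary[1, ], c(41, 1))
  expect_equal(fr_l$v[1, ], c(-1, 0))

  # x-tie broken towards lower y
  pts2 <- tibble::tibble(id = 1:3, x = c(41, 59, 59), y = c(0, 5, 2))
  fr2 <- kernelrows:::init_frontiers(pts2, c(1L, 1L, 1L), +1)
  expect_equal(fr2$boundary[1, ], c(59, 2))
})

test_that("search labels a perfect grid fully with no halved corrections", {
  grid <- tidyr::expand_grid(x = as.numeric(0:20), y = c(0, 10, 20))
  grid <- tibble::as_tibble(grid[, c("x", "y")])
  pts <- dplyr::mutate(grid, id = dplyr::row_number(), .before = 1)
  lab <- ifelse(pts$x >= 8 & pts$x <= 12,
                as.integer(pts$y / 10) + 1L, NA_integer_)
  out <- bidirectional_search(pts, lab, c(lo = 8, hi = 12), theta_T = 10)
  expect_false(anyNA(out$labels))
  expect_equal(out$n_halved, 0L)
  # every point ends in the row of its own y-band
  expect_equal(length(unique(paste(out$labels, pts$y))), 3L)
})

test_that("a far-off stray point stays unlabeled while rows extend past gaps", {
  pts <- tibble::tibble(
    id = 1:12,
    x = c(0:4, 6:10, 8.5, 1.5),
    y = c(rep(0, 10), 100, -70)
  )
  lab <- rep(NA_integer_, 12)
  lab[pts$x >= 3 & pts$x <= 7 & abs(pts$y) < 1] <- 1L
  out <- bidirectional_search(pts, lab, c(lo = 3, hi = 7), theta_T = 10)
  expect_true(all(is.na(out$labels[11:12])))
  expect_false(anyNA(out$labels[1:10]))
})

test_that("assignment is independent of row enumeration order", {
  ear <- simulate_ear(total_rows = 12, twist_rate = 0.02, seed = 8)
  al <- align_principal_axis(ear$points)
  seg <- extract_middle_segment(al, 0.09, min_points = 3)
  rep <- select_row_count(squeeze_points(seg, 1000), rng_seed = 4)
  lab <- transfer_labels(al, seg, rep$labels)
  bounds <- attr(seg, "segment_bounds")

  base <- bidirectional_search(al, lab, bounds, 10)
  set.seed(31)
  for (r in 1:5) {
    perm <- sample(rep$c_star)
    lab_p <- perm[lab]
    out <- bidirectional_search(al, as.integer(lab_p), bounds, 10)
    # same partition up to the applied permutation
    expect_equal(out$labels, perm[base$labels])
  }
})

test_that("frontier x advances monotonically within a directional pass", {
  # instrumented replay: candidates right of the segment, assigned in order
  ear <- simulate_ear(total_rows = 10, twist_rate = 0.02, seed = 5)
  al <- align_principal_axis(ear$points)
  seg <- extract_middle_segment(al, 0.09, min_points = 3)
  rep <- select_row_count(squeeze_points(seg, 1000), rng_seed = 4)
  lab0 <- transfer_labels(al, seg, rep$labels)
  hi <- attr(seg, "segment_bounds")[["hi"]]
  out <- bidirectional_search(al, lab0, attr(seg, "segment_bounds"), 10)
  for (k in unique(lab0[!is.na(lab0)])) {
    added <- which(is.na(lab0) & !is.na(out$labels) & out$labels == k &
                     al$x > hi)
    if (length(added) > 1) {
      # visited in ascending x, so the boundary never retreats
      expect_true(all(diff(sort(al$x[added])) >= 0))
    }
  }
  # conservation: every point is labeled or unlabeled, nothing lost
  expect_equal(sum(!is.na(out$labels)) + sum(is.na(out$labels)), nrow(al))
})

test_that("partial-row recovery distinguishes one band, two bands and dust", {
  # two clear y-bands at one ear end, both running to the tip -> 2 partial rows
  two <- tibble::tibble(
    id = 1:8,
    x = c(100, 110, 120, 130, 101, 111, 121, 131),
    y = c(0, 0.5, 0, 0.5, 50, 50.5, 50, 50.5)
  )
  rec2 <- recover_partial_rows(two, 1:8, t = 1000, rng_seed = 2, x_centre = 0)
  expect_equal(rec2$n_partial, 2L)
  expect_equal(length(unique(paste(rec2$assignment, two$y > 25))), 2L)

  # one curved band on one side: x-disjoint split is vetoed -> 1 partial row
  one <- tibble::tibble(id = 1:6, x = seq(100, 200, by = 20),
                        y = c(0, 1.5, 3.5, 6, 9, 12.5))
  rec1 <- recover_partial_rows(one, 1:6, t = 1000, rng_seed = 2, x_centre = 0)
  expect_equal(rec1$n_partial, 1L)
  expect_false(anyNA(rec1$assignment))

  # fewer than 3 residue points: no partial rows
  rec0 <- recover_partial_rows(one, 1:2, t = 1000, rng_seed = 2)
  expect_equal(rec0$n_partial, 0L)
  expect_true(all(is.na(rec0$assignment)))
  rec_empty <- recover_partial_rows(one, integer(0), t = 1000, rng_seed = 2)
  expect_equal(rec_empty$n_partial, 0L)
})
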