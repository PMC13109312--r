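# Count metrics, row matching, assignment metrics and angle statistics.

test_that("count metrics reproduce the worked arithmetic examples", {
  ident <- count_metrics(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ident$mae, 0)
  expect_equal(ident$mse, 0)
  expect_equal(ident$r2, 1)
  expect_equal(ident$zero_error_rate, 1)

  m <- count_metrics(c(10, 20, 30), c(12, 18, 33))
  expect_equal(m$mae, 7 / 3)
  expect_equal(m$mse, 17 / 3)
  expect_equal(m$r2, 1 - 17 / 237)
  expect_equal(m$zero_error_rate, 0)

  mc <- count_metrics(c(10, 20, 30), c(12, 18, 33), r2 = "conventional")
  expect_equal(mc$r2, 1 - 17 / 200)

  # both denominators give 1 on perfect prediction
  expect_equal(count_metrics(1:4, 1:4, r2 = "conventional")$r2, 1)

  expect_error(count_metrics(1:3, 1:2), class = "kr_bad_input")
  expect_error(count_metrics(numeric(), numeric()), class = "kr_bad_input")
  flat <- count_metrics(c(3, 3), c(4, 4), r2 = "conventional")
  expect_false(flat$r2_defined)
})

test_that("row matching is permutation-invariant and optimal", {
  truth <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  m_id <- match_rows(truth, truth)
  expect_equal(nrow(m_id), 3L)
  expect_equal(sum(m_id$shared), 9L)
  expect_equal(m_id$true_row, m_id$pred_row)

  perm <- c(2, 3, 1)[truth]
  m_perm <- match_rows(truth, perm)
  expect_equal(sum(m_perm$shared), 9L)

  # two true rows merged into one predicted row: one matched pair,
  # one unmatched true row
  merged <- c(1, 1, 1, 1, 1, 1, 2, 2, 2)
  m_merge <- match_rows(truth, merged)
  expect_equal(nrow(m_merge), 2L)
  expect_setequal(m_merge$pred_row, c(1, 2))
  expect_equal(m_merge$shared[m_merge$pred_row == 2], 3L)
})

test_that("matching agrees with exhaustive search on random small tables", {
  set.seed(12)
  for (rep in 1:20) {
    nt <- sample(2:5, 1)
    np <- sample(2:5, 1)
    n <- 40
    truth <- sample(nt, n, replace = TRUE)
    pred <- sample(np, n, replace = TRUE)
    m <- match_rows(truth, pred)
    C <- matrix(0L, nt, np)
    for (i in seq_len(n)) C[truth[i], pred[i]] <- C[truth[i], pred[i]] + 1L
    expect_equal(sum(m$shared), exhaustive_match_value(C))
  }
})

test_that("assignment metrics reproduce the precision/recall/F1 arithmetic", {
  m <- metrics_from_counts(tp = 9, fp = 1, fn = 2)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11)
  expect_equal(m$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))

  truth <- c(1, 1, 1, 2, 2, 2)
  perfect <- assignment_metrics(truth, c(5, 5, 5, 9, 9, 9))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  nothing <- assignment_metrics(truth, rep(NA_integer_, 6))
  expect_equal(nothing$recall, 0)
  expect_true(nothing$degenerate)
})

test_that("swapping predicted and true exchanges precision and recall, not F1", {
  truth <- c(1, 1, 1, 1, 2, 2, 2, NA, NA)
  pred <- c(1, 1, 1, 2, 2, 2, NA, 3, 3)
  fwd <- assignment_metrics(truth, pred)
  rev <- assignment_metrics(pred, truth)
  expect_false(fwd$fp == fwd$fn) # genuinely asymmetric counts
  expect_equal(fwd$fp, rev$fn)
  expect_equal(fwd$fn, rev$fp)
  expect_equal(fwd$precision, rev$recall)
  expect_equal(fwd$recall, rev$precision)
  expect_equal(fwd$f1, rev$f1)
})

test_that("inter-kernel angles match closed forms and the shared angle kernel", {
  flat <- tibble::tibble(x = 0:5, y = rep(2, 6))
  expect_true(all(inter_kernel_angles(flat)$angle == 0))

  right <- tibble::tibble(x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(inter_kernel_angles(right)$angle, 90)

  expect_equal(nrow(inter_kernel_angles(flat[1:2, ])), 0L)
  expect_warning(
    inter_kernel_angles(tibble::tibble(x = c(0, 1, 1), y = c(0, 0, 0))),
    "coincident"
  )

  # cross-check against angle_between on consecutive difference vectors
  set.seed(3)
  row <- tibble::tibble(x = sort(runif(8, 0, 100)), y = rnorm(8))
  ang <- inter_kernel_angles(row)$angle
  ref <- vapply(seq_len(6), function(i) {
    angle_between(
      c(row$x[i + 1] - row$x[i], row$y[i + 1] - row$y[i]),
      c(row$x[i + 2] - row$x[i + 1], row$y[i + 2] - row$y[i + 1])
    )
  }, 1)
  expect_equal(ang, ref, tolerance = 1e-12)
})

test_that("angle histogram uses the standard bins", {
  h <- angle_histogram(c(3, 7, 12, 25, 45))
  expect_equal(h$count, c(2L, 1L, 1L, 0L, 1L))
  expect_equal(sum(h$count), 5L)
  expect_equal(h$percent[1], 40)

  # bin edges: left-closed at 0, right-closed elsewhere
  edge <- angle_histogram(c(0, 10, 10.0001, 20, 40, 40.0001))
  expect_equal(edge$count, c(2L, 2L, 0L, 1L, 1L))
})
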