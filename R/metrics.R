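# Evaluation metrics: count errors, row matching, per-kernel assignment
# precision/recall/F1, and the inter-kernel angle statistic.

#' Count-trait error metrics
#'
#' Mean absolute error, mean squared error, coefficient of determination and
#' zero-error rate between ground-truth and predicted counts. The default
#' `r2` denominator is `sum((mean(truth) - pred)^2)`, the form used for
#' reporting by this pipeline's evaluation protocol; `r2 = "conventional"`
#' uses the textbook `sum((truth - mean(truth))^2)`. Both coincide (R^2 = 1)
#' when predictions equal truth.
#'
#' @param truth,pred Equal-length numeric vectors of per-ear counts.
#' @param r2 Either `"printed"` (default) or `"conventional"`.
#' @return One-row tibble with `n`, `mae`, `mse`, `r2`, `r2_defined`
#'   (FALSE when the chosen denominator is zero) and `zero_error_rate`.
#' @examples
#' count_metrics(c(10, 20, 30), c(12, 18, 33))
#' @export
count_metrics <- function(truth, pred, r2 = c("printed", "conventional")) {
  r2 <- match.arg(r2)
  if (length(truth) != length(pred)) {
    stop_kr("`truth` and `pred` must have equal length.", "kr_bad_input")
  }
  n <- length(truth)
  if (n == 0L) stop_kr("need at least one observation.", "kr_bad_input")
  err <- truth - pred
  denom <- if (r2 == "printed") {
    sum((mean(truth) - pred)^2)
  } else {
    sum((truth - mean(truth))^2)
  }
  r2_defined <- denom > 0
  tibble(
    n = n,
    mae = mean(abs(err)),
    mse = mean(err^2),
    r2 = if (r2_defined) 1 - sum(err^2) / denom else NA_real_,
    r2_defined = r2_defined,
    zero_error_rate = mean(truth == pred)
  )
}

# Exact maximum-weight one-to-one assignment on a contingency matrix C
# (rows x cols), allowing unmatched rows/cols. Bitmask dynamic program over
# the smaller dimension. Returns a list(rows, cols) of matched index pairs.
max_overlap_assignment <- function(C) {
  transposed <- FALSE
  if (ncol(C) > nrow(C)) {
    C <- t(C)
    transposed <- TRUE
  }
  nr <- nrow(C)
  nc <- ncol(C)
  if (nc > 20L) {
    stop_kr("too many row labels for exact matching (> 20).", "kr_bad_input")
  }
  nmask <- bitwShiftL(1L, nc)
  dp <- matrix(0, nr + 1L, nmask)
  choice <- matrix(0L, nr, nmask)    # 0 = row unmatched, j = matched to col j
  for (i in seq_len(nr)) {
    for (mask in 0:(nmask - 1L)) {
      best <- dp[i, mask + 1L]       # leave row i unmatched
      pick <- 0L
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) != 0L) {
          val <- dp[i, mask - bit + 1L] + C[i, j]
          if (val > best) {
            best <- val
            pick <- j
          }
        }
      }
      dp[i + 1L, mask + 1L] <- best
      choice[i, mask + 1L] <- pick
    }
  }
  rows <- integer(0)
  cols <- integer(0)
  mask <- nmask - 1L
  for (i in rev(seq_len(nr))) {
    j <- choice[i, mask + 1L]
    if (j > 0L) {
      rows <- c(i, rows)
      cols <- c(j, cols)
      mask <- mask - bitwShiftL(1L, j - 1L)
    }
  }
  if (transposed) list(rows = cols, cols = rows) else list(rows = rows, cols = cols)
}

#' Match predicted rows to ground-truth rows
#'
#' Finds the one-to-one correspondence between true and predicted row labels
#' that maximizes the total number of shared points (exact maximum-overlap
#' assignment on the contingency table; pairs sharing no point are not
#' matched). `NA` labels (unassigned points) are ignored when counting
#' overlap.
#'
#' @param true_labels,pred_labels Row labels of the same point set
#'   (integers, `NA` allowed).
#' @return Tibble with columns `true_row`, `pred_row`, `shared`.
#' @export
match_rows <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    stop_kr("label vectors must have equal length.", "kr_bad_input")
  }
  ok <- !is.na(true_labels) & !is.na(pred_labels)
  t_lv <- sort(unique(true_labels[!is.na(true_labels)]))
  p_lv <- sort(unique(pred_labels[!is.na(pred_labels)]))
  if (length(t_lv) == 0L || length(p_lv) == 0L || !any(ok)) {
    return(tibble(true_row = integer(), pred_row = integer(),
                  shared = integer()))
  }
  C <- matrix(0L, length(t_lv), length(p_lv))
  ti <- match(true_labels[ok], t_lv)
  pj <- match(pred_labels[ok], p_lv)
  for (i in seq_along(ti)) C[ti[i], pj[i]] <- C[ti[i], pj[i]] + 1L
  sol <- max_overlap_assignment(C)
  shared <- C[cbind(sol$rows, sol$cols)]
  keep <- shared > 0L
  tibble(
    true_row = t_lv[sol$rows[keep]],
    pred_row = p_lv[sol$cols[keep]],
    shared = as.integer(shared[keep])
  )
}

#' Per-kernel row-assignment metrics
#'
#' Scores a predicted row labeling against ground truth as a classification
#' task under the maximum-overlap row correspondence from [match_rows()]:
#' a kernel is a true positive when its predicted row is the match of its
#' true row; a false positive when it is assigned to any other row
#' (including rows with no match); a false negative when it carries a true
#' label but was left unassigned or mis-assigned. Precision, recall and F1
#' are the usual ratios; degenerate ratios (zero denominator) are reported
#' as 0 and flagged.
#'
#' @param true_labels,pred_labels Row labels of the same point set (`NA`
#'   allowed).
#' @param matching Optional precomputed [match_rows()] table.
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `degenerate`.
#' @export
assignment_metrics <- function(true_labels, pred_labels, matching = NULL) {
  if (is.null(matching)) matching <- match_rows(true_labels, pred_labels)
  match_of_true <- matching$pred_row[match(true_labels, matching$true_row)]
  tp <- sum(!is.na(pred_labels) & !is.na(match_of_true) &
              pred_labels == match_of_true)
  fp <- sum(!is.na(pred_labels)) - tp
  fn <- sum(!is.na(true_labels)) - tp
  metrics_from_counts(tp, fp, fn)
}

# Precision/recall/F1 from raw counts (exported for direct use on counts).
#' @rdname assignment_metrics
#' @param tp,fp,fn True positive, false positive and false negative counts.
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  degenerate <- (tp + fp) == 0 || (tp + fn) == 0
  precision <- if ((tp + fp) > 0) tp / (tp + fp) else 0
  recall <- if ((tp + fn) > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         precision = precision, recall = recall, f1 = f1,
         degenerate = degenerate)
}

#' Inter-kernel angles along a row
#'
#' For consecutive kernel triplets `(P1, P2, P3)` taken in axial order, the
#' angle between the vectors `P1->P2` and `P2->P3`, in degrees. Triplets
#' with coincident consecutive points are skipped with a warning. The
#' statistic quantifies row curvature: on real ears the vast majority of
#' these angles fall below 10 degrees, the biological basis for the default
#' `theta_T`.
#'
#' @param points Tibble with columns `x`, `y`: the kernels of one row.
#' @return Tibble with one column `angle` (degrees, in `[0, 180]`).
#' @export
inter_kernel_angles <- function(points) {
  pts <- dplyr::arrange(tibble::as_tibble(points), .data$x, .data$y)
  n <- nrow(pts)
  if (n < 3L) return(tibble(angle = double()))
  angles <- double(0)
  skipped <- 0L
  for (i in seq_len(n - 2L)) {
    v1 <- c(pts$x[i + 1L] - pts$x[i], pts$y[i + 1L] - pts$y[i])
    v2 <- c(pts$x[i + 2L] - pts$x[i + 1L], pts$y[i + 2L] - pts$y[i + 1L])
    if (all(v1 == 0) || all(v2 == 0)) {
      skipped <- skipped + 1L
      next
    }
    angles <- c(angles, angle_between(v1, v2))
  }
  if (skipped > 0L) {
    warn(sprintf("skipped %d triplet(s) with coincident consecutive points.",
                 skipped))
  }
  tibble(angle = angles)
}

#' Inter-kernel angles of every row of a labeled ear
#'
#' @param points Tibble with columns `x`, `y`.
#' @param labels Row labels (`NA` ignored); rows with fewer than 3 points
#'   contribute no angles.
#' @return Tibble with columns `row` and `angle`.
#' @export
ear_angles <- function(points, labels) {
  pts <- tibble::as_tibble(points)
  rows <- sort(unique(labels[!is.na(labels)]))
  purrr::map_dfr(rows, function(k) {
    ang <- inter_kernel_angles(pts[which(!is.na(labels) & labels == k), ])
    if (nrow(ang) == 0L) return(NULL)
    tibble(row = k, angle = ang$angle)
  })
}

#' Histogram of inter-kernel angles over the standard bins
#'
#' Bins: `[0, 10]`, `(10, 20]`, `(20, 30]`, `(30, 40]`, `> 40` degrees.
#'
#' @param angles Numeric vector of angles in degrees.
#' @return Tibble with columns `bin`, `count`, `percent`.
#' @export
angle_histogram <- function(angles) {
  breaks <- c(-1e-9, 10, 20, 30, 40, 180)
  labs <- c("[0,10]", "(10,20]", "(20,30]", "(30,40]", ">40")
  cuts <- cut(angles, breaks = breaks, labels = labs)
  counts <- as.integer(table(cuts))
  tibble(
    bin = labs,
    count = counts,
    percent = if (length(angles) > 0L) 100 * counts / length(angles) else
      rep(NA_real_, length(labs))
  )
}
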