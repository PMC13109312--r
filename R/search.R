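# Bidirectional point searching: extend middle-segment row clusters to both
# ear ends by greedy angular tracing with three position-correction regimes,
# then recover partial rows from the unlabeled residue.

#' Angle between two vectors, in degrees
#'
#' `theta = arccos(v . w / (|v| |w|))`, clamped to `[0, 180]`.
#'
#' @param v,w Numeric vectors of length 2, both nonzero.
#' @return The angle in degrees.
#' @export
angle_between <- function(v, w) {
  nv <- sqrt(sum(v^2))
  nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) {
    stop_kr("angle with a zero vector is undefined.", "kr_undefined_angle")
  }
  cosang <- sum(v * w) / (nv * nw)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Classify a candidate direction and apply the position-correction rule
#'
#' Given a row's running unit direction `v`, a candidate vector `v_new`
#' (boundary point to candidate point) and the base angle threshold
#' `theta_T`, the candidate falls into one of three regimes:
#'
#' * `accept` (`theta_k <= theta_T`): normal row curvature; the direction is
#'   replaced by the normalized candidate vector.
#' * `accept_halved` (`theta_T < theta_k <= 2 * theta_T`): the deviation is
#'   attributed mainly to localization error; the candidate is accepted but
#'   the direction only rotates towards it by half the angle, damping error
#'   propagation. The candidate's coordinates themselves are never moved.
#' * `reject` (`theta_k > 2 * theta_T`): outlier; direction unchanged.
#'
#' @param v Current unit direction of the row.
#' @param v_new Candidate vector (need not be unit length).
#' @param theta_T Base angle threshold in degrees.
#' @return List with `regime` (one of `"accept"`, `"accept_halved"`,
#'   `"reject"`), `theta` (degrees) and `v_updated` (unit vector).
#' @export
classify_and_correct <- function(v, v_new, theta_T) {
  theta <- angle_between(v, v_new)
  if (theta <= theta_T) {
    upd <- v_new / sqrt(sum(v_new^2))
    regime <- "accept"
  } else if (theta <= 2 * theta_T) {
    # rotate v towards v_new by half the angle; sign from the cross product
    cross <- v[1L] * v_new[2L] - v[2L] * v_new[1L]
    sgn <- if (cross >= 0) 1 else -1
    phi <- sgn * 0.5 * theta * pi / 180
    upd <- c(cos(phi) * v[1L] - sin(phi) * v[2L],
             sin(phi) * v[1L] + cos(phi) * v[2L])
    upd <- upd / sqrt(sum(upd^2))
    regime <- "accept_halved"
  } else {
    upd <- v
    regime <- "reject"
  }
  list(regime = regime, theta = theta, v_updated = upd)
}

# Initial frontier of every row for one search direction.
# labels: integer row labels (NA = unassigned), aligned to pts rows.
# direction: +1 (rightward) or -1 (leftward).
# Boundary = extreme-x member; x-ties broken by lower y, then lower index.
init_frontiers <- function(pts, labels, direction) {
  rows <- sort(unique(labels[!is.na(labels)]))
  if (length(rows) == 0L) {
    stop_kr("no labeled rows to initialize frontiers from.", "kr_internal")
  }
  boundary <- matrix(NA_real_, length(rows), 2L)
  for (i in seq_along(rows)) {
    members <- which(!is.na(labels) & labels == rows[i])
    if (length(members) == 0L) {
      stop_kr("empty row encountered while initializing frontiers.",
              "kr_internal")
    }
    ord <- order(direction * pts$x[members], pts$y[members], members,
                 decreasing = c(TRUE, FALSE, FALSE), method = "radix")
    b <- members[ord[1L]]
    boundary[i, ] <- c(pts$x[b], pts$y[b])
  }
  list(
    rows = rows,
    boundary = boundary,
    v = matrix(rep(c(direction, 0), each = length(rows)), ncol = 2L)
  )
}

# One directional pass of the greedy angular search. Candidates are the
# unassigned points beyond the given segment edge, visited by increasing
# axial distance from that edge. Each candidate is evaluated against every
# row frontier and assigned to the admissible row with the smallest angle;
# ties go to the lower row id. Returns the updated label vector and the
# number of halved-angle corrections applied.
search_pass <- function(pts, labels, edge, direction, theta_T) {
  fr <- init_frontiers(pts, labels, direction)
  if (direction > 0) {
    cand <- which(is.na(labels) & pts$x > edge)
  } else {
    cand <- which(is.na(labels) & pts$x < edge)
  }
  if (length(cand) == 0L) {
    return(list(labels = labels, n_halved = 0L))
  }
  ord <- order(direction * pts$x[cand], pts$y[cand], cand, method = "radix")
  cand <- cand[ord]
  n_halved <- 0L
  for (i in cand) {
    p <- c(pts$x[i], pts$y[i])
    best_k <- 0L
    best_theta <- Inf
    for (k in seq_along(fr$rows)) {
      vn <- p - fr$boundary[k, ]
      if (all(vn == 0)) { # coincides with the boundary point: trivially accept
        th <- 0
      } else {
        th <- angle_between(fr$v[k, ], vn)
      }
      if (th <= 2 * theta_T && th < best_theta) {
        best_theta <- th
        best_k <- k
      }
    }
    if (best_k > 0L) {
      vn <- p - fr$boundary[best_k, ]
      if (!all(vn == 0)) {
        upd <- classify_and_correct(fr$v[best_k, ], vn, theta_T)
        if (upd$regime == "accept_halved") n_halved <- n_halved + 1L
        fr$v[best_k, ] <- upd$v_updated
      }
      fr$boundary[best_k, ] <- p
      labels[i] <- fr$rows[best_k]
    }
  }
  list(labels = labels, n_halved = n_halved)
}

#' Extend row clusters to both ear ends
#'
#' Runs the greedy angular search rightward and leftward from the labeled
#' middle segment. Unassigned points beyond the segment edges are visited by
#' increasing axial distance and assigned to the admissible row frontier
#' (angle within `2 * theta_T`) with the smallest angle; the row's boundary
#' point and running direction update with every assignment. Points whose
#' angle exceeds `2 * theta_T` for every row stay unassigned. Coordinates
#' are never modified: corrections act on the direction state only.
#'
#' @param points Aligned tibble with columns `id`, `x`, `y`.
#' @param labels Integer row labels (NA = unassigned), e.g. from
#'   [transfer_labels()].
#' @param segment_bounds Length-2 numeric `c(lo, hi)`: the axial bounds of
#'   the labeled middle segment.
#' @param theta_T Base angle threshold in degrees.
#' @return A list with `labels` (updated vector) and `n_halved` (number of
#'   halved-angle corrections across both passes).
#' @export
bidirectional_search <- function(points, labels, segment_bounds, theta_T) {
  right <- search_pass(points, labels, segment_bounds[["hi"]], +1, theta_T)
  left <- search_pass(points, right$labels, segment_bounds[["lo"]], -1, theta_T)
  list(labels = left$labels, n_halved = right$n_halved + left$n_halved)
}

#' Recover partial rows from the unlabeled residue
#'
#' Partial rows appear at the ear silhouette edges where the spiral brings a
#' row only partly into view. The unlabeled residue left by the search is
#' squeezed and clustered once more with 2-means: when the split is strongly
#' separated (mean silhouette above `min_split_silhouette`) the residue
#' yields two partial rows, otherwise a single partial row. Residues of
#' fewer than 3 points yield no partial row, and any recovered row with
#' fewer than 2 members is discarded back to the outliers.
#'
#' A 2-means split is additionally vetoed when its two clusters occupy
#' disjoint axial ranges on the same side of the ear centre: that signature
#' means a single curved partial row was cut in half along its length.
#' Two genuine partial rows either sit at opposite ear ends, or — when they
#' share an end — both run to the ear tip and so overlap axially.
#'
#' @param points Aligned tibble with columns `id`, `x`, `y`.
#' @param residue_idx Integer indices (into `points`) of the unlabeled residue.
#' @param t Squeeze factor.
#' @param rng_seed Integer seed for the 2-means fit.
#' @param restarts K-means restarts.
#' @param min_split_silhouette Separation required to declare two partial
#'   rows (see [unicorn_params()]).
#' @param x_centre Axial coordinate of the ear centre (used by the
#'   same-side veto); defaults to the residue midrange.
#' @return A list with `assignment` (integer vector aligned to
#'   `residue_idx`: partial-row number or NA for outliers) and `n_partial`
#'   (0, 1 or 2).
#' @export
recover_partial_rows <- function(points, residue_idx, t, rng_seed,
                                 restarts = 10L, min_split_silhouette = 0.75,
                                 x_centre = NULL) {
  m <- length(residue_idx)
  if (m < 3L) {
    return(list(assignment = rep(NA_integer_, m), n_partial = 0L))
  }
  res <- points[residue_idx, , drop = FALSE]
  if (is.null(x_centre)) x_centre <- (min(res$x) + max(res$x)) / 2
  sq <- squeeze_points(res, t)
  X <- cbind(sq$x, sq$y)
  km <- fit_kmeans(X, 2L, rng_seed, restarts)
  groups <- rep(1L, m)
  if (!is.null(km) && length(unique(km$cluster)) == 2L) {
    s2 <- mean_silhouette(sq, km$cluster)
    a <- res$x[km$cluster == 1L]
    b <- res$x[km$cluster == 2L]
    x_disjoint <- max(a) < min(b) || max(b) < min(a)
    same_side <- (min(res$x) > x_centre) || (max(res$x) < x_centre)
    if (s2 > min_split_silhouette && !(x_disjoint && same_side)) {
      groups <- as.integer(km$cluster)
    }
  }
  sizes <- tabulate(groups)
  keep <- which(sizes >= 2L)
  assignment <- rep(NA_integer_, m)
  for (j in seq_along(keep)) {
    assignment[groups == keep[j]] <- j
  }
  list(assignment = assignment, n_partial = length(keep))
}
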