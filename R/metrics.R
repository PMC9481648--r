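# Trajectory similarity metrics: travelled distance, pointwise linear/angular
# curve distances, averaging and forward/return symmetry.

#' Travelled distance (start-to-goal straight line)
#'
#' Euclidean distance between the first and last samples of a trajectory.
#' This is deliberately not arc length: it measures how far the entity had to
#' go, not the path it chose.
#'
#' @param traj a [trajectory()].
#' @return distance (m).
#' @export
travelled_distance <- function(traj) {
  stopifnot(inherits(traj, "copair_traj"))
  sqrt((traj$x[traj$n] - traj$x[1L])^2 + (traj$y[traj$n] - traj$y[1L])^2)
}

#' Linear and angular distance between two curves
#'
#' For two trajectories time-normalized to the same number of samples N,
#' the linear distance is the mean over samples of the pointwise euclidean
#' distance, and the angular distance is the mean absolute pointwise
#' difference of the unwrapped headings:
#' \deqn{d_{xy} = \frac{1}{N}\sum_i \sqrt{(x_{1,i}-x_{2,i})^2+(y_{1,i}-y_{2,i})^2},
#'       \quad d_\theta = \frac{1}{N}\sum_i |\theta_{1,i}-\theta_{2,i}|.}
#' Smaller distances mean closer paths.
#'
#' @param X1,X2 trajectories with equal sample counts.
#' @return a list with `d_xy` (m) and `d_theta` (rad).
#' @export
curve_distance <- function(X1, X2) {
  stopifnot(inherits(X1, "copair_traj"), inherits(X2, "copair_traj"))
  if (X1$n != X2$n)
    stop(sprintf("mismatched sample counts (%d vs %d); normalize both trajectories first",
                 X1$n, X2$n), call. = FALSE)
  list(d_xy = mean(sqrt((X1$x - X2$x)^2 + (X1$y - X2$y)^2)),
       d_theta = mean(abs(X1$theta - X2$theta)))
}

#' Arithmetic average of trajectories
#'
#' Per-sample arithmetic mean of `x`, `y` and the unwrapped heading over a set
#' of trajectories normalized to the same sample count. Averaging across table
#' configurations is refused: the two configurations differ by a half-turn and
#' their mean is meaningless.
#'
#' @param trajs non-empty list of trajectories with identical sample counts.
#'   Optional `config` attributes on the elements are checked for consistency.
#' @return the average trajectory.
#' @export
average_trajectory <- function(trajs) {
  if (length(trajs) == 0L) stop("cannot average an empty list", call. = FALSE)
  stopifnot(all(vapply(trajs, inherits, TRUE, "copair_traj")))
  ns <- vapply(trajs, function(z) z$n, 1L)
  if (length(unique(ns)) != 1L)
    stop("all trajectories must share the same sample count", call. = FALSE)
  cfg <- unlist(lapply(trajs, attr, "config"))
  if (length(unique(cfg)) > 1L)
    stop("refusing to average across table configurations", call. = FALSE)
  x <- rowMeans(vapply(trajs, function(z) z$x, numeric(ns[1L])))
  y <- rowMeans(vapply(trajs, function(z) z$y, numeric(ns[1L])))
  th <- rowMeans(vapply(trajs, function(z) z$theta, numeric(ns[1L])))
  out <- trajectory(x, y, th, t = trajs[[1L]]$t, entity = trajs[[1L]]$entity,
                    normalized = trajs[[1L]]$normalized)
  if (length(cfg) > 0L) attr(out, "config") <- cfg[1L]
  out
}

#' Forward/return symmetry distances
#'
#' Distances between a forward path and its reversed return path. The smaller
#' they are, the more symmetrical the two paths.
#'
#' @param forward,return_ trajectories normalized to the same sample count.
#' @return a list with `d_xy` (m) and `d_theta` (rad).
#' @export
symmetry_distances <- function(forward, return_) {
  curve_distance(forward, reverse_trajectory(return_))
}
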