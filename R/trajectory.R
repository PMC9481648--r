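# Planar trajectory container and time normalization.

#' Planar trajectory of one entity
#'
#' A trajectory stores the horizontal position `(x, y)` of an entity's centre
#' of mass and its heading `theta` over time. The heading is stored unwrapped:
#' consecutive samples never differ by more than pi, so pointwise angular
#' differences and arithmetic averages are meaningful.
#'
#' @param x,y numeric vectors, positions (m) in the global frame.
#' @param theta numeric vector, heading (rad); unwrapped on construction.
#' @param t time stamps: seconds for raw recordings, or percent in
#'   `[0, 100]` once time-normalized. Defaults to a 0..100 grid.
#' @param entity one of `"subject1"`, `"subject2"`, `"table"`.
#' @param normalized logical, `TRUE` when `t` is normalized time.
#' @return an object of class `copair_traj` with fields `x`, `y`, `theta`,
#'   `t`, `n`, `entity`, `normalized`.
#' @examples
#' tr <- trajectory(x = 0:10, y = rep(0, 11), theta = rep(0, 11))
#' travelled_distance(tr)
#' @export
trajectory <- function(x, y, theta, t = NULL, entity = "subject1",
                       normalized = is.null(t)) {
  n <- length(x)
  if (n < 2L) stop("a trajectory needs at least 2 samples", call. = FALSE)
  if (length(y) != n || length(theta) != n)
    stop("x, y, theta must have equal length", call. = FALSE)
  if (is.null(t)) t <- seq(0, 100, length.out = n)
  if (length(t) != n) stop("t must match the sample count", call. = FALSE)
  entity <- match.arg(entity, c("subject1", "subject2", "table"))
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         theta = unwrap_angle(as.numeric(theta)),
         t = as.numeric(t), n = n, entity = entity,
         normalized = isTRUE(normalized)),
    class = "copair_traj")
}

#' @export
print.copair_traj <- function(x, ...) {
  cat(sprintf("<copair_traj> %s, %d samples (%s), start (%.2f, %.2f, %.2f), end (%.2f, %.2f, %.2f)\n",
              x$entity, x$n, if (x$normalized) "normalized" else "raw time",
              x$x[1], x$y[1], x$theta[1],
              x$x[x$n], x$y[x$n], x$theta[x$n]))
  invisible(x)
}

#' Resample a trajectory on normalized time
#'
#' Linearly interpolates `x`, `y` and the unwrapped `theta` onto `n_out`
#' equally spaced points of normalized time in `[0, 100]` percent. The first
#' and last poses are preserved exactly.
#'
#' @param traj a [trajectory()].
#' @param n_out number of output samples (default 500).
#' @return a normalized `copair_traj` with `n_out` samples.
#' @export
normalize_time <- function(traj, n_out = 500L) {
  stopifnot(inherits(traj, "copair_traj"))
  if (n_out < 2L) stop("n_out must be at least 2", call. = FALSE)
  s_in <- (traj$t - traj$t[1L]) / (traj$t[traj$n] - traj$t[1L]) * 100
  s_out <- seq(0, 100, length.out = n_out)
  out <- trajectory(
    x = stats::approx(s_in, traj$x, xout = s_out, ties = "ordered")$y,
    y = stats::approx(s_in, traj$y, xout = s_out, ties = "ordered")$y,
    theta = stats::approx(s_in, traj$theta, xout = s_out, ties = "ordered")$y,
    t = s_out, entity = traj$entity, normalized = TRUE)
  # endpoints exact by construction of the interpolation grid
  out$x[c(1L, n_out)] <- traj$x[c(1L, traj$n)]
  out$y[c(1L, n_out)] <- traj$y[c(1L, traj$n)]
  out$theta[c(1L, n_out)] <- traj$theta[c(1L, traj$n)]
  out
}

#' Reverse the sample order of a trajectory
#'
#' Supports the forward/return symmetry comparison: a return path is compared
#' against the reversed forward path. The heading is re-unwrapped after
#' reversal.
#'
#' @param traj a [trajectory()].
#' @return the reversed trajectory.
#' @export
reverse_trajectory <- function(traj) {
  stopifnot(inherits(traj, "copair_traj"))
  idx <- rev(seq_len(traj$n))
  t <- if (traj$normalized) traj$t else max(traj$t) - rev(traj$t) + min(traj$t)
  trajectory(traj$x[idx], traj$y[idx], traj$theta[idx], t = t,
             entity = traj$entity, normalized = traj$normalized)
}

#' Write / read a trajectory as JSON
#'
#' Schema: `{entity, n, t_norm[], x[], y[], theta[]}`.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `read_trajectory_json` returns a `copair_traj`;
#'   `write_trajectory_json` returns `path` invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  stopifnot(inherits(traj, "copair_traj"))
  obj <- list(entity = traj$entity, n = traj$n, t_norm = traj$t,
              x = traj$x, y = traj$y, theta = traj$theta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_json
#' @export
read_trajectory_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trajectory(obj$x, obj$y, obj$theta, t = obj$t_norm, entity = obj$entity,
             normalized = TRUE)
}
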