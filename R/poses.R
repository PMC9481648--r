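# Planar pose extraction: pelvis centre of mass + heading, and table pose
# from three corner markers.

#' Pelvis planar pose from four pelvis markers
#'
#' The horizontal centre of mass is approximated by the centroid of the four
#' pelvis markers (left/right antero- and postero-superior iliac spines). The
#' heading is the horizontal direction of the vector from the PSIS midpoint to
#' the ASIS midpoint (the anatomical forward direction of the pelvis),
#' unwrapped along the trajectory.
#'
#' @param pelvis_markers a [marker_series()] with exactly the labels
#'   `LASI`, `RASI`, `LPSI`, `RPSI`.
#' @param entity entity tag for the returned trajectory.
#' @return a raw-time [trajectory()].
#' @export
pelvis_com_pose <- function(pelvis_markers, entity = "subject1") {
  stopifnot(inherits(pelvis_markers, "marker_series"))
  need <- c("LASI", "RASI", "LPSI", "RPSI")
  missing <- setdiff(need, pelvis_markers$labels)
  if (length(missing) > 0L)
    stop(sprintf("missing pelvis marker label(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  g <- function(lab, d) pelvis_markers$xyz[, d, lab]
  asis_x <- (g("LASI", 1) + g("RASI", 1)) / 2
  asis_y <- (g("LASI", 2) + g("RASI", 2)) / 2
  psis_x <- (g("LPSI", 1) + g("RPSI", 1)) / 2
  psis_y <- (g("LPSI", 2) + g("RPSI", 2)) / 2
  dx <- asis_x - psis_x
  dy <- asis_y - psis_y
  if (any(dx^2 + dy^2 < 1e-12))
    stop("degenerate pelvis geometry: ASIS and PSIS midpoints coincide", call. = FALSE)
  x <- (g("LASI", 1) + g("RASI", 1) + g("LPSI", 1) + g("RPSI", 1)) / 4
  y <- (g("LASI", 2) + g("RASI", 2) + g("LPSI", 2) + g("RPSI", 2)) / 4
  trajectory(x, y, atan2(dy, dx), t = pelvis_markers$t, entity = entity,
             normalized = FALSE)
}

#' Table planar pose from three corner markers
#'
#' The table top is a rigid `length x width` rectangle (1.22 x 0.8 m) with
#' markers on three of its four corners, ordered around the rectangle
#' (P1 - P2 - P3 adjacent). The fourth corner is reconstructed from rigid
#' geometry as `P1 + P3 - P2`; the pose is the centre of the four corners with
#' the heading of the long axis, unwrapped.
#'
#' @param corner_markers a [marker_series()] with exactly 3 markers ordered
#'   around the rectangle (consecutive markers share an edge).
#' @param length,width table top dimensions (m).
#' @param tol tolerance on edge-length consistency (m, default 0.05).
#' @return a raw-time [trajectory()] with `entity = "table"`.
#' @export
table_pose <- function(corner_markers, length = 1.22, width = 0.8, tol = 0.05) {
  stopifnot(inherits(corner_markers, "marker_series"))
  if (dim(corner_markers$xyz)[3L] != 3L)
    stop("exactly 3 corner markers are required", call. = FALSE)
  p1 <- corner_markers$xyz[, 1:2, 1L, drop = FALSE][, , 1L]
  p2 <- corner_markers$xyz[, 1:2, 2L, drop = FALSE][, , 1L]
  p3 <- corner_markers$xyz[, 1:2, 3L, drop = FALSE][, , 1L]
  if (corner_markers$n == 1L) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3) }
  e12 <- sqrt(rowSums((p2 - p1)^2))
  e23 <- sqrt(rowSums((p3 - p2)^2))
  ok <- function(e) (abs(e - length) < tol) | (abs(e - width) < tol)
  if (!all(ok(e12) & ok(e23)))
    stop(sprintf("inter-marker distances inconsistent with a %.2f x %.2f m table (tolerance %.2f m)",
                 length, width, tol), call. = FALSE)
  p4 <- p1 + p3 - p2
  cx <- (p1[, 1] + p2[, 1] + p3[, 1] + p4[, 1]) / 4
  cy <- (p1[, 2] + p2[, 2] + p3[, 2] + p4[, 2]) / 4
  # the long axis is the edge pair whose length matches `length`
  long_is_12 <- abs(mean(e12) - length) < abs(mean(e23) - length)
  ax <- if (long_is_12) p2 - p1 else p3 - p2
  theta <- atan2(ax[, 2], ax[, 1])
  trajectory(cx, cy, theta, t = corner_markers$t, entity = "table",
             normalized = FALSE)
}
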