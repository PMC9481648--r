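# Raw marker handling: container, CSV reader, gap interpolation, zero-phase
# low-pass filtering and lift-based trial segmentation.

#' Marker time series container
#'
#' Holds synchronous 3D positions of a set of labelled markers, as recorded by
#' an optical motion-capture system (nominally 200 Hz).
#'
#' @param t time stamps (s), strictly increasing and uniform.
#' @param xyz numeric array `n x 3 x n_markers` of positions (m). Gaps are
#'   flagged as `NA`, never silently dropped.
#' @param labels character vector of marker names, one per array slice.
#' @param rate sampling rate (Hz); inferred from `t` when missing.
#' @return an object of class `marker_series`.
#' @export
marker_series <- function(t, xyz, labels, rate = NULL) {
  xyz <- as.array(xyz)
  if (length(dim(xyz)) != 3L || dim(xyz)[2L] != 3L)
    stop("xyz must be an n x 3 x n_markers array", call. = FALSE)
  n <- dim(xyz)[1L]
  if (length(t) != n) stop("t must match the number of samples", call. = FALSE)
  if (length(labels) != dim(xyz)[3L])
    stop("one label per marker is required", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"), labels)
  structure(list(t = as.numeric(t), xyz = xyz, labels = as.character(labels),
                 rate = rate, n = n),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %d samples at %.1f Hz, markers: %s\n",
              x$n, x$rate, paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Read a trial CSV into a marker series
#'
#' Expected dialect: one row per sample, a mandatory header, a `time` column in
#' seconds and `<marker>_x`, `<marker>_y`, `<marker>_z` columns in metres.
#'
#' @param path CSV file path.
#' @return a [marker_series()].
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV must have a 'time' column", call. = FALSE)
  coord_cols <- grep("_[xyz]$", names(df), value = TRUE)
  labels <- unique(sub("_[xyz]$", "", coord_cols))
  xyz <- array(NA_real_, dim = c(nrow(df), 3L, length(labels)))
  for (m in seq_along(labels)) {
    for (d in 1:3) {
      col <- paste0(labels[m], "_", c("x", "y", "z")[d])
      if (!col %in% names(df))
        stop(sprintf("missing column '%s'", col), call. = FALSE)
      xyz[, d, m] <- df[[col]]
    }
  }
  marker_series(df$time, xyz, labels)
}

#' Interpolate short marker gaps
#'
#' Linearly fills `NA` runs of at most `max_gap` samples per coordinate.
#' Longer runs are surfaced as an error naming the marker: long occlusions
#' invalidate a trial rather than being imputed.
#'
#' @param series a [marker_series()].
#' @param max_gap longest run of missing samples to fill (default 10).
#' @return the gap-filled series.
#' @export
interpolate_gaps <- function(series, max_gap = 10L) {
  stopifnot(inherits(series, "marker_series"))
  xyz <- series$xyz
  for (m in seq_along(series$labels)) {
    for (d in 1:3) {
      v <- xyz[, d, m]
      if (!anyNA(v)) next
      r <- rle(is.na(v))
      runs <- r$lengths[r$values]
      if (any(runs > max_gap) || is.na(v[1L]) || is.na(v[length(v)]))
        stop(sprintf("marker '%s': gap longer than %d samples (or at a boundary)",
                     series$labels[m], max_gap), call. = FALSE)
      xyz[, d, m] <- stats::approx(series$t[!is.na(v)], v[!is.na(v)],
                                   xout = series$t)$y
    }
  }
  marker_series(series$t, xyz, series$labels, series$rate)
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a zero phase-shift (forward-backward) low-pass Butterworth filter to
#' every coordinate of every marker. Defaults match kinematic practice: fourth
#' order, 10 Hz cutoff at 200 Hz sampling.
#'
#' @param series a [marker_series()] without `NA` inside the filtered span.
#' @param cutoff cutoff frequency (Hz); must be below the Nyquist frequency.
#' @param order filter order; even and positive.
#' @return the filtered series (same length).
#' @export
lowpass_filter <- function(series, cutoff = 10, order = 4L) {
  stopifnot(inherits(series, "marker_series"))
  if (order <= 0L || order %% 2L != 0L)
    stop("order must be even and positive", call. = FALSE)
  nyquist <- series$rate / 2
  if (cutoff >= nyquist)
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyquist),
         call. = FALSE)
  if (series$rate <= 2 * cutoff)
    stop("sampling rate must exceed twice the cutoff", call. = FALSE)
  na_markers <- series$labels[apply(series$xyz, 3L, anyNA)]
  if (length(na_markers) > 0L)
    stop(sprintf("NA runs inside signal for marker(s): %s (interpolate gaps first)",
                 paste(na_markers, collapse = ", ")), call. = FALSE)
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  xyz <- series$xyz
  for (m in seq_along(series$labels)) {
    for (d in 1:3) {
      v <- xyz[, d, m]
      # filtfilt on the fluctuation about the mean keeps DC exactly
      mu <- mean(v)
      xyz[, d, m] <- signal::filtfilt(bf, v - mu) + mu
    }
  }
  marker_series(series$t, xyz, series$labels, series$rate)
}

#' Reference table height to the floor
#'
#' The floor height is taken as the minimum height observed during the first
#' `window` seconds of the trial (table at rest on the floor); it is subtracted
#' so that the lift threshold is expressed "above the floor".
#'
#' @param z table height series (m).
#' @param rate sampling rate (Hz).
#' @param window initial rest window (s, default 0.5).
#' @return `z` minus the floor reference.
#' @export
floor_reference <- function(z, rate, window = 0.5) {
  k <- max(1L, min(length(z), round(window * rate)))
  z - min(z[seq_len(k)])
}

#' Segment a trial by table lift height
#'
#' A carriage trial contains exactly two lifts of the table: the forward path
#' and the return path. Lift onsets/offsets are detected as the table height
#' exceeding, then returning below, a threshold above the floor (5 mm by
#' default).
#'
#' @param table_z table height above the floor (m); see [floor_reference()].
#' @param threshold lift threshold (m), default 0.005.
#' @return a `trial_segments` list with `forward = c(onset, offset)`,
#'   `return_ = c(onset, offset)` and `approach = c(1, forward onset)`
#'   (sample indices).
#' @export
segment_by_table_height <- function(table_z, threshold = 0.005) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  up <- table_z > threshold
  n <- length(up)
  onsets <- which(diff(c(FALSE, up)) == 1L)
  offsets <- integer(0)
  segs <- list()
  for (on in onsets) {
    off <- which(!up & seq_len(n) > on)
    if (length(off) == 0L) next   # lift never returns to the floor
    segs[[length(segs) + 1L]] <- c(onset = on, offset = off[1L])
  }
  if (length(segs) < 2L)
    stop("incomplete trial: fewer than two table lifts detected", call. = FALSE)
  if (length(segs) > 2L)
    stop(sprintf("more than two table lifts detected; candidate segments: %s (merge before segmenting)",
                 paste(vapply(segs, function(s) sprintf("[%d,%d]", s[1], s[2]), ""),
                       collapse = " ")), call. = FALSE)
  structure(list(forward = segs[[1L]], return_ = segs[[2L]],
                 approach = c(start = 1L, onset = segs[[1L]][["onset"]])),
            class = "trial_segments")
}
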