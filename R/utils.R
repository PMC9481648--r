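# Internal helpers shared across modules.

#' Wrap angles to (-pi, pi]
#'
#' @param a numeric vector of angles (rad).
#' @return angles mapped into `(-pi, pi]`.
#' @keywords internal
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Unwrap a continuous angle signal
#'
#' Removes the +/- 2*pi jumps a wrapped representation introduces, so that
#' consecutive differences are below pi in magnitude.
#'
#' @param theta numeric vector of angles (rad).
#' @return unwrapped angles; first element unchanged.
#' @keywords internal
unwrap_angle <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- wrap_angle(diff(theta))
  cumsum(c(theta[1L], d))
}

# Deterministic 31-bit hash of a master seed and trial coordinates, so any
# trial is regenerable in isolation.
hash_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 104729
  for (p in parts) {
    h <- (h * 31 + (as.numeric(p) %% 1e9)) %% 2147483647
  }
  as.integer(h)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
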