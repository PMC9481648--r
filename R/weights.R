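# Cost weights of the coupled optimal-control model.

#' Cost weights of the coupled OC model
#'
#' `alpha` holds the 11 running-cost weights: `alpha[1]` (alpha_0) the constant
#' time-pressure term, `alpha[2..7]` (alpha_1..alpha_6) the squared-control
#' efforts of Subject 1 then Subject 2 (forward, lateral, angular
#' acceleration), `alpha[8..9]` (alpha_7, alpha_8) the squared
#' bearing-to-goal/heading errors, `alpha[10]` (alpha_9) the separation
#' barrier and `alpha[11]` (alpha_10) the facing barriers. `beta` holds the 4
#' terminal-cost weights: positions, orientations, linear velocities, angular
#' velocities. The cost scale is arbitrary: multiplying all weights by a
#' positive constant does not change the optimal trajectories.
#'
#' @param alpha numeric vector of 11 nonnegative running-cost weights.
#' @param beta numeric vector of 4 nonnegative terminal-cost weights.
#' @return an object of class `cost_weights`.
#' @export
cost_weights <- function(alpha, beta) {
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  if (length(alpha) != 11L) stop("alpha must have 11 components", call. = FALSE)
  if (length(beta) != 4L) stop("beta must have 4 components", call. = FALSE)
  if (any(alpha < 0) || any(beta < 0))
    stop("weights must be nonnegative", call. = FALSE)
  if (all(alpha == 0) && all(beta == 0))
    stop("weights must not be all zero", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "cost_weights")
}

#' @export
print.cost_weights <- function(x, ...) {
  cat("<cost_weights>\n  alpha:", paste(signif(x$alpha, 4), collapse = " "),
      "\n  beta: ", paste(signif(x$beta, 4), collapse = " "), "\n")
  invisible(x)
}

#' Reference cost weights
#'
#' The weight set identified by inverse optimal control on the measured
#' Scenario-3 average trajectories:
#' alpha = (3.85, 2.29, 10.37, 0.10, 2.7, 8.99, 3.00, 10.42, 1.81e-6, 0.50,
#' 0.03), beta = (19.77, 30.24, 8.77, 9.15).
#'
#' @return a [cost_weights()] object.
#' @export
reference_weights <- function() {
  cost_weights(
    alpha = c(3.85, 2.29, 10.37, 0.10, 2.7, 8.99, 3.00, 10.42, 1.81e-6, 0.50, 0.03),
    beta = c(19.77, 30.24, 8.77, 9.15))
}

#' Normalize weights to a fixed total
#'
#' The OC cost scale is arbitrary, so weights are only identifiable up to a
#' positive factor. For reporting and comparison they are rescaled so that
#' `sum(alpha) + sum(beta) = total`.
#'
#' @param weights a [cost_weights()].
#' @param total target sum (default 100).
#' @return rescaled [cost_weights()].
#' @export
normalize_weights <- function(weights, total = 100) {
  stopifnot(inherits(weights, "cost_weights"))
  s <- sum(weights$alpha) + sum(weights$beta)
  cost_weights(weights$alpha * total / s, weights$beta * total / s)
}

#' Read / write cost weights as YAML
#'
#' @param weights a [cost_weights()]; @param path file path.
#' @return `read_weights_yaml` returns a `cost_weights`;
#'   `write_weights_yaml` returns `path` invisibly.
#' @export
write_weights_yaml <- function(weights, path) {
  stopifnot(inherits(weights, "cost_weights"))
  yaml::write_yaml(list(alpha = weights$alpha, beta = weights$beta), path)
  invisible(path)
}

#' @rdname write_weights_yaml
#' @export
read_weights_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cost_weights(obj$alpha, obj$beta)
}
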