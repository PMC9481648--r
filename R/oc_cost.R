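# Running and terminal costs of the coupled OC model, with the exponential
# barrier couplings and their derivatives for the DDP solver.
#
# State layout (12): (x1, y1, th1, vf1, vo1, om1, x2, y2, th2, vf2, vo2, om2).
# Control layout (6): (u11, u12, u13, u21, u22, u23).

IDX1 <- 1:6
IDX2 <- 7:12

#' Separation barrier between the two carriers
#'
#' The table forces the carriers to stay between `d_min` and `d_max` apart.
#' The barrier is 0 inside the open band and grows exponentially with the
#' distance to the nearest bound outside it:
#' `exp(min(|d - d_max|, |d - d_min|)) - 1`.
#'
#' @param state 12-component model state (see [dynamics()]).
#' @param d_min,d_max separation bounds (m), defaults 1.6 and 2.1.
#' @return barrier value (nonnegative scalar).
#' @export
chi_barrier <- function(state, d_min = 1.6, d_max = 2.1) {
  stopifnot(d_min < d_max)
  d <- sqrt((state[1L] - state[7L])^2 + (state[2L] - state[8L])^2)
  if (d > d_min && d < d_max) 0 else exp(min(abs(d - d_max), abs(d - d_min))) - 1
}

#' Facing barrier of one carrier
#'
#' Each carrier roughly faces the other across the table: the angle
#' `gamma_i` between carrier i's heading and the direction from carrier i to
#' carrier j must stay below `gamma_max`. The barrier is 0 below the bound and
#' `exp(gamma_i - gamma_max) - 1` beyond it.
#'
#' @param state 12-component model state.
#' @param i subject index (1 or 2).
#' @param gamma_max facing bound (rad), default `pi/3`.
#' @return barrier value (nonnegative scalar).
#' @export
xi_barrier <- function(state, i, gamma_max = pi / 3) {
  o_i <- if (i == 1L) 0L else 6L
  o_j <- if (i == 1L) 6L else 0L
  dx <- state[o_j + 1L] - state[o_i + 1L]
  dy <- state[o_j + 2L] - state[o_i + 2L]
  if (dx^2 + dy^2 < 1e-12)
    stop("coincident subjects: facing angle undefined", call. = FALSE)
  gam <- abs(wrap_angle(atan2(dy, dx) - state[o_i + 3L]))
  if (gam < gamma_max) 0 else exp(gam - gamma_max) - 1
}

#' Bearing-to-goal heading error
#'
#' `psi_i` is the difference between the bearing from carrier i's current
#' position to its goal point and its current heading, computed with the
#' two-argument arctangent and wrapped to `(-pi, pi]`. At the goal point the
#' bearing is undefined and `psi` is defined as 0 (the goal-alignment
#' incentive must vanish once the goal is reached).
#'
#' @param state 12-component model state.
#' @param x_f goal pose vector `(x1f, y1f, th1f, x2f, y2f, th2f)`.
#' @param i subject index (1 or 2).
#' @return heading error (rad).
#' @export
heading_error_psi <- function(state, x_f, i) {
  o <- if (i == 1L) 0L else 6L
  of <- if (i == 1L) 0L else 3L
  dx <- x_f[of + 1L] - state[o + 1L]
  dy <- x_f[of + 2L] - state[o + 2L]
  if (dx^2 + dy^2 < 1e-12) return(0)
  wrap_angle(atan2(dy, dx) - state[o + 3L])
}

#' Running cost of the coupled OC model
#'
#' \deqn{\phi_r = \alpha_0 + \sum_{i,k}\alpha_{(i-1)3+k} u_{i,k}^2
#'   + \alpha_7\psi_1^2 + \alpha_8\psi_2^2 + \alpha_9\chi
#'   + \alpha_{10}(\xi_1+\xi_2)}
#'
#' @param state 12-component model state.
#' @param control 6-component control.
#' @param weights a [cost_weights()].
#' @param x_f goal pose vector `(x1f, y1f, th1f, x2f, y2f, th2f)`.
#' @param d_min,d_max,gamma_max barrier bounds.
#' @return scalar cost (per unit time).
#' @export
running_cost <- function(state, control, weights, x_f,
                         d_min = 1.6, d_max = 2.1, gamma_max = pi / 3) {
  a <- weights$alpha
  a[1L] +
    sum(a[2:7] * control^2) +
    a[8L] * heading_error_psi(state, x_f, 1L)^2 +
    a[9L] * heading_error_psi(state, x_f, 2L)^2 +
    a[10L] * chi_barrier(state, d_min, d_max) +
    a[11L] * (xi_barrier(state, 1L, gamma_max) + xi_barrier(state, 2L, gamma_max))
}

#' Terminal cost of the coupled OC model
#'
#' Penalizes squared terminal position and orientation errors of both
#' carriers and their squared terminal linear and angular velocities:
#' \deqn{\phi_t = \beta_0\sum_i \|p_{i,f}-p_i(T)\|^2 +
#'   \beta_1\sum_i(\theta_{i,f}-\theta_i(T))^2 +
#'   \beta_2\sum_i(v_{i,forw}^2+v_{i,orth}^2) + \beta_3\sum_i\omega_i^2}
#'
#' @inheritParams running_cost
#' @return scalar terminal cost.
#' @export
terminal_cost <- function(state, weights, x_f) {
  b <- weights$beta
  b[1L] * ((x_f[1L] - state[1L])^2 + (x_f[2L] - state[2L])^2 +
           (x_f[4L] - state[7L])^2 + (x_f[5L] - state[8L])^2) +
    b[2L] * ((x_f[3L] - state[3L])^2 + (x_f[6L] - state[9L])^2) +
    b[3L] * (state[4L]^2 + state[5L]^2 + state[10L]^2 + state[11L]^2) +
    b[4L] * (state[6L]^2 + state[12L]^2)
}

# ---- analytic derivatives (internal, used by the DDP backward pass) --------
#
# Gauss-Newton convention: for terms w * g(s)^2 the Hessian keeps only
# 2 w grad(g) grad(g)', and for barriers w * (exp(m(s)) - 1) only
# w exp(m) grad(m) grad(m)'. Barrier gradients at the activation kink use the
# one-sided outside derivative.

# gradient (12) of psi_i; zero at the goal point
psi_grad <- function(state, x_f, i) {
  g <- numeric(12L)
  o <- if (i == 1L) 0L else 6L
  of <- if (i == 1L) 0L else 3L
  dx <- x_f[of + 1L] - state[o + 1L]
  dy <- x_f[of + 2L] - state[o + 2L]
  r2 <- dx^2 + dy^2
  if (r2 < 1e-12) return(g)
  g[o + 1L] <- dy / r2
  g[o + 2L] <- -dx / r2
  g[o + 3L] <- -1
  g
}

# value, gradient (12) of chi; one-sided outside derivative at the bounds
chi_val_grad <- function(state, d_min, d_max) {
  ddx <- state[1L] - state[7L]
  ddy <- state[2L] - state[8L]
  d <- sqrt(ddx^2 + ddy^2)
  g <- numeric(12L)
  if (d > d_min && d < d_max) return(list(val = 0, grad = g))
  side <- if (d >= d_max) 1 else -1     # dm/dd
  m <- if (d >= d_max) d - d_max else d_min - d
  e <- exp(m)
  dd <- numeric(12L)
  if (d > 1e-12) {
    dd[1L] <- ddx / d; dd[2L] <- ddy / d
    dd[7L] <- -ddx / d; dd[8L] <- -ddy / d
  }
  list(val = e - 1, grad = e * side * dd, expm = e, gm = side * dd)
}

# value, gradient (12) of xi_i
xi_val_grad <- function(state, i, gamma_max) {
  o_i <- if (i == 1L) 0L else 6L
  o_j <- if (i == 1L) 6L else 0L
  dx <- state[o_j + 1L] - state[o_i + 1L]
  dy <- state[o_j + 2L] - state[o_i + 2L]
  r2 <- dx^2 + dy^2
  g <- numeric(12L)
  if (r2 < 1e-12) return(list(val = 0, grad = g))
  delta <- wrap_angle(atan2(dy, dx) - state[o_i + 3L])
  gam <- abs(delta)
  if (gam < gamma_max) return(list(val = 0, grad = g))
  sgn <- if (delta >= 0) 1 else -1
  gd <- numeric(12L)                    # gradient of delta
  gd[o_i + 1L] <- dy / r2
  gd[o_i + 2L] <- -dx / r2
  gd[o_j + 1L] <- -dy / r2
  gd[o_j + 2L] <- dx / r2
  gd[o_i + 3L] <- -1
  e <- exp(gam - gamma_max)
  list(val = e - 1, grad = e * sgn * gd, expm = e, gm = sgn * gd)
}

# running cost derivatives at one knot: l, lx (12), lu (6), lxx (12x12 GN),
# luu (6x6); lux is identically zero. All scaled by dt by the caller.
running_cost_derivs <- function(state, control, weights, x_f,
                                d_min, d_max, gamma_max) {
  a <- weights$alpha
  lx <- numeric(12L)
  lxx <- matrix(0, 12L, 12L)
  l <- a[1L] + sum(a[2:7] * control^2)
  for (i in 1:2) {
    ai <- a[7L + i]
    if (ai > 0) {
      ps <- heading_error_psi(state, x_f, i)
      gp <- psi_grad(state, x_f, i)
      l <- l + ai * ps^2
      lx <- lx + 2 * ai * ps * gp
      lxx <- lxx + 2 * ai * tcrossprod(gp)
    } else {
      l <- l + ai * heading_error_psi(state, x_f, i)^2
    }
  }
  ch <- chi_val_grad(state, d_min, d_max)
  l <- l + a[10L] * ch$val
  if (ch$val > 0 || !is.null(ch$expm)) {
    lx <- lx + a[10L] * ch$grad
    if (!is.null(ch$expm))
      lxx <- lxx + a[10L] * ch$expm * tcrossprod(ch$gm)
  }
  for (i in 1:2) {
    xv <- xi_val_grad(state, i, gamma_max)
    l <- l + a[11L] * xv$val
    if (!is.null(xv$expm)) {
      lx <- lx + a[11L] * xv$grad
      lxx <- lxx + a[11L] * xv$expm * tcrossprod(xv$gm)
    }
  }
  list(l = l, lx = lx, lu = 2 * a[2:7] * control,
       lxx = lxx, luu = diag(2 * a[2:7], 6L))
}

# terminal cost derivatives: l, lx (12), lxx (12x12, exact - cost is quadratic)
terminal_cost_derivs <- function(state, weights, x_f) {
  b <- weights$beta
  lx <- numeric(12L)
  hd <- numeric(12L)
  lx[c(1L, 2L)] <- -2 * b[1L] * (x_f[1:2] - state[1:2])
  lx[c(7L, 8L)] <- -2 * b[1L] * (x_f[4:5] - state[7:8])
  lx[3L] <- -2 * b[2L] * (x_f[3L] - state[3L])
  lx[9L] <- -2 * b[2L] * (x_f[6L] - state[9L])
  lx[c(4L, 5L, 10L, 11L)] <- 2 * b[3L] * state[c(4L, 5L, 10L, 11L)]
  lx[c(6L, 12L)] <- 2 * b[4L] * state[c(6L, 12L)]
  hd[c(1L, 2L, 7L, 8L)] <- 2 * b[1L]
  hd[c(3L, 9L)] <- 2 * b[2L]
  hd[c(4L, 5L, 10L, 11L)] <- 2 * b[3L]
  hd[c(6L, 12L)] <- 2 * b[4L]
  list(l = terminal_cost(state, weights, x_f), lx = lx, lxx = diag(hd, 12L))
}
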