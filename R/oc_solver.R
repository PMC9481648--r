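# Coupled two-agent holonomic dynamics and the DDP/iLQR trajectory optimizer.

#' Coupled holonomic dynamics
#'
#' Each carrier is a planar holonomic agent: its centre of mass moves with a
#' forward velocity `v_forw` along the pelvis heading and a lateral velocity
#' `v_orth` orthogonal to it (side-stepping is allowed, unlike a unicycle),
#' and the heading rotates at `omega`. The controls are the six accelerations
#' `(u_i1, u_i2, u_i3) = (dv_forw, dv_orth, domega)/dt` of the two carriers.
#'
#' State layout: `(x1, y1, th1, vf1, vo1, om1, x2, y2, th2, vf2, vo2, om2)`.
#'
#' @param state 12-component state.
#' @param control 6-component control.
#' @return the 12-component time derivative of the state.
#' @export
dynamics <- function(state, control) {
  stop_if_not_finite(state, "state")
  stop_if_not_finite(control, "control")
  d <- numeric(12L)
  for (i in 0:1) {
    o <- 6L * i
    th <- state[o + 3L]; vf <- state[o + 4L]; vo <- state[o + 5L]
    d[o + 1L] <- cos(th) * vf - sin(th) * vo
    d[o + 2L] <- sin(th) * vf + cos(th) * vo
    d[o + 3L] <- state[o + 6L]
    d[o + 4L] <- control[3L * i + 1L]
    d[o + 5L] <- control[3L * i + 2L]
    d[o + 6L] <- control[3L * i + 3L]
  }
  d
}

# discrete-time Jacobians of x' = x + dt f(x, u)
dyn_jac <- function(state, dt) {
  A <- diag(12L)
  for (i in 0:1) {
    o <- 6L * i
    th <- state[o + 3L]; vf <- state[o + 4L]; vo <- state[o + 5L]
    A[o + 1L, o + 3L] <- dt * (-sin(th) * vf - cos(th) * vo)
    A[o + 1L, o + 4L] <- dt * cos(th)
    A[o + 1L, o + 5L] <- dt * (-sin(th))
    A[o + 2L, o + 3L] <- dt * (cos(th) * vf - sin(th) * vo)
    A[o + 2L, o + 4L] <- dt * sin(th)
    A[o + 2L, o + 5L] <- dt * cos(th)
    A[o + 3L, o + 6L] <- dt
  }
  A
}

dyn_B <- function(dt) {
  B <- matrix(0, 12L, 6L)
  B[4L, 1L] <- B[5L, 2L] <- B[6L, 3L] <- dt
  B[10L, 4L] <- B[11L, 5L] <- B[12L, 6L] <- dt
  B
}

# Euler rollout of a control sequence: U is N x 6, returns (N+1) x 12
rollout <- function(x0, U, dt) {
  N <- nrow(U)
  X <- matrix(0, N + 1L, 12L)
  X[1L, ] <- x0
  for (k in seq_len(N)) X[k + 1L, ] <- X[k, ] + dt * dynamics(X[k, ], U[k, ])
  X
}

# total discretized cost of a rollout
trajectory_cost <- function(X, U, weights, x_f, dt, d_min, d_max, gamma_max) {
  N <- nrow(U)
  run <- 0
  for (k in seq_len(N))
    run <- run + running_cost(X[k, ], U[k, ], weights, x_f, d_min, d_max, gamma_max)
  dt * run + terminal_cost(X[N + 1L, ], weights, x_f)
}

#' Coupled OC problem definition
#'
#' @param x_s 12-component start state (velocities default to zero when a
#'   6-component pose vector is given).
#' @param x_f goal pose vector `(x1f, y1f, th1f, x2f, y2f, th2f)`.
#' @param T horizon (s), or `"free"` to let [select_horizon()] choose it.
#' @param dt integration step (s), default 0.05.
#' @param d_min,d_max separation bounds (m), defaults 1.6 and 2.1.
#' @param gamma_max facing bound (rad), default `pi/3`.
#' @return an object of class `oc_problem`.
#' @export
oc_problem <- function(x_s, x_f, T = "free", dt = 0.05,
                       d_min = 1.6, d_max = 2.1, gamma_max = pi / 3) {
  if (length(x_s) == 6L)
    x_s <- c(x_s[1:3], 0, 0, 0, x_s[4:6], 0, 0, 0)
  stopifnot(length(x_s) == 12L, length(x_f) == 6L, dt > 0, d_min < d_max)
  d0 <- sqrt((x_s[1L] - x_s[7L])^2 + (x_s[2L] - x_s[8L])^2)
  if (d0 < d_min || d0 > d_max)
    stop(sprintf("start separation %.3f m outside [%g, %g] m", d0, d_min, d_max),
         call. = FALSE)
  structure(list(x_s = as.numeric(x_s), x_f = as.numeric(x_f), T = T, dt = dt,
                 d_min = d_min, d_max = d_max, gamma_max = gamma_max),
            class = "oc_problem")
}

#' OC problem for a study goal
#'
#' Builds the coupled OC problem for one goal, configuration and direction.
#' For a return path the roles are kept (Subject 1 stays Subject 1); role
#' switching for inverse optimal control is handled by
#' [role_switch_return()]. Goal headings are chosen in the branch nearest the
#' start headings so the terminal orientation error is measured on the
#' continuous angle.
#'
#' @param goal a [goal_spec()].
#' @param config `"A"` or `"B"`.
#' @param direction `"forward"` or `"return"`.
#' @param T horizon (s) or `"free"`; the default `"auto"` uses the
#'   straight-line distance at a 1.2 m/s nominal speed plus a 2 s maneuver
#'   allowance.
#' @param dt integration step (s).
#' @return an [oc_problem()].
#' @export
goal_problem <- function(goal, config = "A", direction = c("forward", "return"),
                         T = "auto", dt = 0.05) {
  stopifnot(inherits(goal, "goal_spec"))
  direction <- match.arg(direction)
  tg <- goal[[paste0("table_goal_", config)]]
  from <- if (direction == "forward") goal$table_start else tg
  to <- if (direction == "forward") tg else goal$table_start
  s <- subject_poses(from, goal$grip_offset)
  g <- subject_poses(to, goal$grip_offset)
  near <- function(target, ref) ref + wrap_angle(target - ref)
  x_s <- c(s$subject1, s$subject2)
  x_f <- c(g$subject1[1:2], near(g$subject1[[3L]], s$subject1[[3L]]),
           g$subject2[1:2], near(g$subject2[[3L]], s$subject2[[3L]]))
  if (identical(T, "auto"))
    T <- round((goal$global_distance / 1.2 + 2.0) / dt) * dt
  oc_problem(x_s, x_f, T = T, dt = dt)
}

# Straight-line warm start: poses interpolated with a trapezoidal speed
# profile (accelerate over T/4, cruise, decelerate over T/4), converted to
# body-frame velocities, controls by finite differences, then rolled out so
# the nominal trajectory is dynamically feasible.
warm_start <- function(problem) {
  N <- max(2L, round(problem$T / problem$dt))
  dt <- problem$dt
  tau <- seq(0, 1, length.out = N + 1L)
  # trapezoidal profile with ramp fraction 1/4: s in [0,1], ds/dtau
  a <- 0.25
  vmax <- 1 / (1 - a)
  sfun <- function(u) ifelse(u < a, vmax * u^2 / (2 * a),
                      ifelse(u < 1 - a, vmax * (u - a / 2),
                             1 - vmax * (1 - u)^2 / (2 * a)))
  dsfun <- function(u) ifelse(u < a, vmax * u / a,
                       ifelse(u < 1 - a, vmax, vmax * (1 - u) / a))
  s <- sfun(tau); ds <- dsfun(tau) / problem$T
  U <- matrix(0, N, 6L)
  vel <- matrix(0, N + 1L, 3L * 2L)
  for (i in 0:1) {
    o <- 6L * i; of <- 3L * i
    p0 <- problem$x_s[o + 1:3]
    p1 <- problem$x_f[of + 1:3]
    th <- p0[3L] + s * (p1[3L] - p0[3L])
    vx <- ds * (p1[1L] - p0[1L])
    vy <- ds * (p1[2L] - p0[2L])
    vel[, 3L * i + 1L] <- cos(th) * vx + sin(th) * vy
    vel[, 3L * i + 2L] <- -sin(th) * vx + cos(th) * vy
    vel[, 3L * i + 3L] <- ds * (p1[3L] - p0[3L])
  }
  for (k in seq_len(N)) U[k, ] <- (vel[k + 1L, ] - vel[k, ]) / dt
  # ds(0) = 0, so the profile is consistent with the zero start velocities
  list(U = U, X = rollout(problem$x_s, U, dt))
}

#' Solve the coupled OC problem by differential dynamic programming
#'
#' Iterative LQ (DDP) optimizer: backward Riccati-like passes over the
#' linearized dynamics and Gauss-Newton cost expansions with Levenberg
#' regularization, forward passes with a backtracking line search, starting
#' from a straight-line warm start. Convergence is declared when the relative
#' cost decrease falls below `tol` (default 1e-6) or after `max_iter`
#' iterations.
#'
#' @param problem an [oc_problem()] with a numeric horizon (see
#'   [select_horizon()] for free-time problems).
#' @param weights a [cost_weights()].
#' @param max_iter iteration cap (default 500).
#' @param tol relative cost-decrease tolerance.
#' @param n_out samples of the returned normalized trajectories (default 500).
#' @param error_on_failure if `TRUE`, raise an error (carrying the cost trace)
#'   instead of returning the last iterate when the iteration cap is hit
#'   without convergence.
#' @param init optional `N x 6` control matrix used as the starting iterate
#'   (e.g. a cached solution when re-solving under nearby weights); ignored
#'   when it does not beat the warm start.
#' @return a list of class `oc_solution`: `subject1` and `subject2`
#'   normalized trajectories, `X` (raw knots), `U`, `cost`, `warm_cost`,
#'   `iterations`, `converged`, `terminal_error` (per-subject position and
#'   angle misses), `chi_zero_fraction`, `cost_trace`.
#' @export
solve_oc <- function(problem, weights, max_iter = 500L, tol = 1e-6,
                     n_out = 500L, error_on_failure = FALSE,
                     init = NULL) {
  stopifnot(inherits(problem, "oc_problem"), inherits(weights, "cost_weights"))
  if (!is.numeric(problem$T))
    stop("horizon is free: resolve it with select_horizon() first", call. = FALSE)
  dt <- problem$dt
  N <- max(2L, round(problem$T / dt))
  ws <- warm_start(problem)
  warm_cost <- trajectory_cost(ws$X, ws$U, weights, problem$x_f, dt,
                               problem$d_min, problem$d_max, problem$gamma_max)
  if (!is.null(init) && nrow(init) == N) {
    U <- init
    X <- rollout(problem$x_s, U, dt)
    cost <- trajectory_cost(X, U, weights, problem$x_f, dt,
                            problem$d_min, problem$d_max, problem$gamma_max)
    if (!is.finite(cost) || cost > warm_cost) { U <- ws$U; X <- ws$X; cost <- warm_cost }
  } else {
    U <- ws$U; X <- ws$X; cost <- warm_cost
  }
  B <- dyn_B(dt)
  mu <- 1e-6
  cost_trace <- cost
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # cost expansions along the nominal trajectory
    term <- terminal_cost_derivs(X[N + 1L, ], weights, problem$x_f)
    Vx <- term$lx
    Vxx <- term$lxx
    kff <- matrix(0, N, 6L)
    Kfb <- vector("list", N)
    d1 <- 0; d2 <- 0
    diverged <- FALSE
    for (k in N:1) {
      rc <- running_cost_derivs(X[k, ], U[k, ], weights, problem$x_f,
                                problem$d_min, problem$d_max, problem$gamma_max)
      A <- dyn_jac(X[k, ], dt)
      Qx <- dt * rc$lx + crossprod(A, Vx)
      Qu <- dt * rc$lu + crossprod(B, Vx)
      VxxA <- Vxx %*% A
      Qxx <- dt * rc$lxx + crossprod(A, VxxA)
      Quu <- dt * rc$luu + crossprod(B, Vxx %*% B) + diag(mu, 6L)
      Qux <- crossprod(B, VxxA)
      ch <- tryCatch(chol(Quu), error = function(e) NULL)
      if (is.null(ch)) { diverged <- TRUE; break }
      kK <- backsolve(ch, forwardsolve(t(ch), cbind(Qu, Qux)))
      kff[k, ] <- -kK[, 1L]
      Kfb[[k]] <- -kK[, -1L, drop = FALSE]
      d1 <- d1 + sum(kff[k, ] * Qu)
      d2 <- d2 + 0.5 * sum(kff[k, ] * (Quu %*% kff[k, ]))
      Vx <- Qx + crossprod(Kfb[[k]], Quu %*% kff[k, ]) +
        crossprod(Kfb[[k]], Qu) + crossprod(Qux, kff[k, ])
      Vxx <- Qxx + crossprod(Kfb[[k]], Quu %*% Kfb[[k]]) +
        crossprod(Kfb[[k]], Qux) + crossprod(Qux, Kfb[[k]])
      Vxx <- (Vxx + t(Vxx)) / 2
    }
    if (diverged) {
      mu <- mu * 10
      if (mu > 1e10) break
      next
    }
    # forward pass with backtracking line search
    improved <- FALSE
    for (eps in 2^(0:-10)) {
      Un <- U
      Xn <- matrix(0, N + 1L, 12L)
      Xn[1L, ] <- problem$x_s
      for (k in seq_len(N)) {
        Un[k, ] <- U[k, ] + eps * kff[k, ] + Kfb[[k]] %*% (Xn[k, ] - X[k, ])
        Xn[k + 1L, ] <- Xn[k, ] + dt * dynamics(Xn[k, ], Un[k, ])
      }
      cn <- trajectory_cost(Xn, Un, weights, problem$x_f, dt,
                            problem$d_min, problem$d_max, problem$gamma_max)
      if (is.finite(cn) && cn < cost) {
        rel <- (cost - cn) / max(1e-12, abs(cost))
        U <- Un; X <- Xn; cost <- cn
        improved <- TRUE
        mu <- max(mu / 5, 1e-9)
        cost_trace <- c(cost_trace, cost)
        if (rel < tol) converged <- TRUE
        break
      }
    }
    if (!improved) {
      mu <- mu * 10
      if (mu > 1e10) { converged <- TRUE; break }  # no further descent possible
    }
    if (converged) break
  }
  if (!converged && error_on_failure) {
    msg <- sprintf("DDP did not converge in %d iterations (last cost %.6g)",
                   max_iter, cost)
    cond <- simpleError(msg)
    cond$cost_trace <- cost_trace
    stop(cond)
  }
  t_raw <- seq(0, problem$T, length.out = N + 1L)
  mk <- function(cols, entity)
    normalize_time(trajectory(X[, cols[1L]], X[, cols[2L]], X[, cols[3L]],
                              t = t_raw, entity = entity, normalized = FALSE),
                   n_out = n_out)
  sep <- sqrt((X[, 1L] - X[, 7L])^2 + (X[, 2L] - X[, 8L])^2)
  chi_vals <- vapply(seq_len(N + 1L), function(k)
    chi_barrier(X[k, ], problem$d_min, problem$d_max), 1)
  term_err <- c(
    pos1 = sqrt((X[N + 1L, 1L] - problem$x_f[1L])^2 + (X[N + 1L, 2L] - problem$x_f[2L])^2),
    pos2 = sqrt((X[N + 1L, 7L] - problem$x_f[4L])^2 + (X[N + 1L, 8L] - problem$x_f[5L])^2),
    ang1 = abs(X[N + 1L, 3L] - problem$x_f[3L]),
    ang2 = abs(X[N + 1L, 9L] - problem$x_f[6L]))
  structure(list(
    subject1 = mk(1:3, "subject1"), subject2 = mk(7:9, "subject2"),
    X = X, U = U, t = t_raw, cost = cost, warm_cost = warm_cost,
    iterations = it, converged = converged, terminal_error = term_err,
    chi_zero_fraction = mean(chi_vals == 0),
    mean_separation = mean(sep), cost_trace = cost_trace,
    problem = problem), class = "oc_solution")
}

#' @export
print.oc_solution <- function(x, ...) {
  cat(sprintf("<oc_solution> T = %.2f s, cost %.4f (warm %.4f), %d iterations%s\n",
              x$problem$T, x$cost, x$warm_cost, x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  terminal miss: %.3f / %.3f m, %.3f / %.3f rad; chi = 0 on %.1f%% of samples\n",
              x$terminal_error[["pos1"]], x$terminal_error[["pos2"]],
              x$terminal_error[["ang1"]], x$terminal_error[["ang2"]],
              100 * x$chi_zero_fraction))
  invisible(x)
}

#' Resolve a free final time by grid search
#'
#' The travel time is part of the minimization. The fixed-horizon problem is
#' solved on a grid of candidate horizons and the horizon with the lowest
#' total cost is returned. The default grid spans 0.6 to 1.6 times the
#' nominal time `T0 = straight-line distance / 1.2 m/s` in 0.5 s steps.
#'
#' @param problem an [oc_problem()] (its `T` field is ignored).
#' @param weights a [cost_weights()].
#' @param t_grid optional numeric grid of horizons (s).
#' @param ... passed to [solve_oc()].
#' @return list with `T` (selected horizon, s), `costs` (per-candidate), and
#'   `solution` (the best [solve_oc()] result).
#' @export
select_horizon <- function(problem, weights, t_grid = NULL, ...) {
  stopifnot(inherits(problem, "oc_problem"))
  if (is.null(t_grid)) {
    mid_s <- c(mean(problem$x_s[c(1L, 7L)]), mean(problem$x_s[c(2L, 8L)]))
    mid_f <- c(mean(problem$x_f[c(1L, 4L)]), mean(problem$x_f[c(2L, 5L)]))
    T0 <- sqrt(sum((mid_f - mid_s)^2)) / 1.2
    t_grid <- seq(0.6 * T0, 1.6 * T0, by = 0.5)
  }
  if (length(t_grid) == 0L) stop("empty horizon grid", call. = FALSE)
  best <- NULL
  costs <- rep(NA_real_, length(t_grid))
  for (i in seq_along(t_grid)) {
    p <- problem
    p$T <- t_grid[i]
    sol <- tryCatch(solve_oc(p, weights, ...), error = function(e) NULL)
    if (is.null(sol)) next
    costs[i] <- sol$cost
    if (is.null(best) || sol$cost < best$cost) best <- sol
  }
  if (is.null(best)) stop("all horizon candidates failed to solve", call. = FALSE)
  list(T = best$problem$T, costs = costs, t_grid = t_grid, solution = best)
}
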