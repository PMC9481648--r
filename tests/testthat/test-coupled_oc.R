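# Coupled OC model: dynamics, barrier costs, DDP solver, horizon selection.

state0 <- function(x1 = 0, y1 = 0, th1 = 0, vf1 = 0, vo1 = 0, om1 = 0,
                   x2 = 1.8, y2 = 0, th2 = pi, vf2 = 0, vo2 = 0, om2 = 0)
  c(x1, y1, th1, vf1, vo1, om1, x2, y2, th2, vf2, vo2, om2)

test_that("dynamics implement the holonomic model exactly", {
  s <- state0(th1 = 0, vf1 = 1)
  d <- dynamics(s, rep(0, 6))
  expect_equal(d[1:3], c(1, 0, 0))

  s2 <- state0(th1 = pi / 2, vf1 = 0, vo1 = 1)
  d2 <- dynamics(s2, rep(0, 6))
  expect_equal(d2[1:2], c(-1, 0), tolerance = 1e-12)

  u <- c(0.1, -0.2, 0.3, 0.4, -0.5, 0.6)
  d3 <- dynamics(state0(vf1 = 0.7, om2 = -0.1), u)
  expect_equal(d3[c(4:6, 10:12)], u)       # integrator chain

  expect_error(dynamics(c(state0()[-1], NaN), rep(0, 6)), "non-finite")
})

test_that("separation barrier has the exponential form with a dead band", {
  expect_equal(chi_barrier(state0(x2 = 1.85)), 0, tolerance = 1e-12)
  expect_equal(chi_barrier(state0(x2 = 2.2)), exp(0.1) - 1, tolerance = 1e-12)
  expect_equal(chi_barrier(state0(x2 = 1.5)), exp(0.1) - 1, tolerance = 1e-12)
  # continuity at the activation boundaries
  for (eps in 10^(-3:-7)) {
    expect_lt(chi_barrier(state0(x2 = 2.1 + eps)), exp(eps) - 1 + 1e-12)
    expect_lt(chi_barrier(state0(x2 = 1.6 - eps)), exp(eps) - 1 + 1e-12)
  }
})

test_that("facing barrier activates beyond the angular bound", {
  # facing each other exactly: both barriers vanish
  expect_equal(xi_barrier(state0(), 1), 0)
  expect_equal(xi_barrier(state0(), 2), 0)
  # gamma = pi/3 + 0.2
  s <- state0(th1 = -(pi / 3 + 0.2))
  expect_equal(xi_barrier(s, 1), exp(0.2) - 1, tolerance = 1e-12)
  for (eps in 10^(-3:-7))
    expect_lt(xi_barrier(state0(th1 = -(pi / 3 + eps)), 1), exp(eps) - 1 + 1e-12)
  expect_error(xi_barrier(state0(x2 = 0, y2 = 0, th2 = 0), 1), "coincident")
})

test_that("bearing-to-goal error wraps correctly", {
  xf <- c(1, 0, 0, 10, 0, pi)
  expect_equal(heading_error_psi(state0(), xf, 1), 0)
  xf2 <- c(0, 1, 0, 10, 0, pi)
  expect_equal(heading_error_psi(state0(), xf2, 1), pi / 2)
  xf3 <- c(-1, 0, 0, 10, 0, pi)
  expect_equal(heading_error_psi(state0(th1 = pi), xf3, 1), 0)
  # at the goal point the error is defined as zero
  xf4 <- c(0, 0, 0, 10, 0, pi)
  expect_equal(heading_error_psi(state0(), xf4, 1), 0)
})

test_that("running and terminal costs match the weighted forms", {
  w <- reference_weights()
  # subject 1 faces its goal ahead; subject 2 walks backward, so its goal
  # lies behind it and the bearing matches its pi heading
  xf <- c(10, 0, 0, -8.2, 0, pi)
  # U = 0, psi = 0, barriers inactive: only alpha_0 survives
  s <- state0()
  expect_equal(running_cost(s, rep(0, 6), w, xf), w$alpha[1], tolerance = 1e-12)

  w1 <- cost_weights(c(0, 1, rep(0, 9)), c(0, 0, 0, 1))
  expect_equal(running_cost(s, c(2, 0, 0, 0, 0, 0), w1, xf), 4)

  # terminal: at the goal with zero velocities the cost vanishes
  sT <- c(10, 0, 0, 0, 0, 0, -8.2, 0, pi, 0, 0, 0)
  expect_equal(terminal_cost(sT, w, xf), 0)
  w2 <- cost_weights(c(1, rep(0, 10)), c(2, 0, 0, 0))
  sT2 <- sT; sT2[1] <- 9   # subject 1 offset by (1, 0)
  expect_equal(terminal_cost(sT2, w2, xf), 2)

  # positivity with nonnegative weights
  set.seed(4)
  for (k in 1:50) {
    s_r <- state0() + stats::rnorm(12, sd = 0.3)
    u_r <- stats::rnorm(6)
    expect_gte(running_cost(s_r, u_r, w, xf), 0)
    expect_gte(terminal_cost(s_r, w, xf), 0)
  }
})

test_that("cost derivatives agree with finite differences", {
  set.seed(8)
  w <- reference_weights()
  xf <- c(3, 1, 0.4, 4.5, 1.4, pi + 0.4)
  for (k in 1:20) {
    s <- state0(x1 = 0.3, y1 = 0.2) + stats::rnorm(12, sd = 0.4)
    u <- stats::rnorm(6)
    der <- copair:::running_cost_derivs(s, u, w, xf, 1.6, 2.1, pi / 3)
    num <- vapply(1:12, function(i) {
      h <- 1e-6; sp <- s; sm <- s; sp[i] <- s[i] + h; sm[i] <- s[i] - h
      (running_cost(sp, u, w, xf) - running_cost(sm, u, w, xf)) / (2 * h)
    }, 1)
    expect_equal(der$lx, num, tolerance = 1e-4)
    tder <- copair:::terminal_cost_derivs(s, w, xf)
    tnum <- vapply(1:12, function(i) {
      h <- 1e-6; sp <- s; sm <- s; sp[i] <- s[i] + h; sm[i] <- s[i] - h
      (terminal_cost(sp, w, xf) - terminal_cost(sm, w, xf)) / (2 * h)
    }, 1)
    expect_equal(tder$lx, tnum, tolerance = 1e-4)
  }
})

test_that("problem construction validates the start separation", {
  expect_error(oc_problem(c(0, 0, 0, 5, 0, pi), c(0, 0, 0, 5, 0, pi)),
               "separation")
  p <- oc_problem(c(0, 0, 0, 1.8, 0, pi), c(4, 0, 0, 5.8, 0, pi), T = 4)
  expect_equal(p$d_min, 1.6)
  expect_equal(p$d_max, 2.1)
  expect_equal(p$gamma_max, pi / 3)
})

test_that("a goal identical to the start yields a near-stationary solution", {
  w <- reference_weights()
  p <- oc_problem(c(0, 0, 0, 1.8, 0, pi), c(0, 0, 0, 1.8, 0, pi),
                  T = 3, dt = 0.05)
  sol <- solve_oc(p, w)
  expect_equal(sol$cost, w$alpha[1] * 3, tolerance = 0.01)
  expect_lt(max(abs(sol$subject1$x)), 0.05)
})

test_that("the solver beats the warm start and respects the dynamics", {
  w <- reference_weights()
  goal <- goal_spec(1, planar_pose(4, 0, 0))
  p <- goal_problem(goal, "A", "forward", dt = 0.05)
  sol <- solve_oc(p, w)
  expect_true(sol$converged)
  expect_lte(sol$cost, sol$warm_cost)
  # rollout consistency: the stored knots satisfy the Euler dynamics
  res <- 0
  for (k in seq_len(nrow(sol$U))) {
    pred <- sol$X[k, ] + p$dt * dynamics(sol$X[k, ], sol$U[k, ])
    res <- max(res, max(abs(sol$X[k + 1, ] - pred)))
  }
  expect_lt(res, 1e-8)
  # total cost is bounded below by the time-pressure term
  expect_gte(sol$cost, w$alpha[1] * p$T - 1e-9)
  # the straight carriage keeps the pair coupled the whole way
  expect_gte(sol$chi_zero_fraction, 0.95)
  expect_true(sol$mean_separation > 1.6 && sol$mean_separation < 2.1)
})

test_that("horizon selection follows the time pressure", {
  goal <- goal_spec(1, planar_pose(3, 0, 0))
  base <- goal_problem(goal, "A", "forward", dt = 0.1)
  grid <- c(2.5, 3.5, 4.5)
  # no time pressure, no bearing cost: longer horizons can only help
  w_free <- cost_weights(c(0, 1, 1, 1, 1, 1, 1, 0, 0, 0.5, 0.03),
                         c(19.77, 30.24, 8.77, 9.15))
  sel <- select_horizon(base, w_free, t_grid = grid)
  expect_equal(sel$T, max(grid))
  expect_true(all(diff(sel$costs) <= 1e-6))
  # heavy time pressure: the shortest horizon wins
  w_rush <- cost_weights(c(50, 1, 1, 1, 1, 1, 1, 0, 0, 0.5, 0.03),
                         c(19.77, 30.24, 8.77, 9.15))
  sel2 <- select_horizon(base, w_rush, t_grid = grid)
  expect_equal(sel2$T, min(grid))
})
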