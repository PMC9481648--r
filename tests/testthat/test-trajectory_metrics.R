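# Curve distances, averaging, symmetry, configuration optimality.

test_that("travelled distance uses endpoints only", {
  same <- trajectory(c(0, 1, 0), c(0, 1, 0), rep(0, 3))
  expect_equal(travelled_distance(same), 0)
  tri <- trajectory(c(0, 3), c(0, 4), c(0, 0))
  expect_equal(travelled_distance(tri), 5)
  # a curved path between the same endpoints gives the same value
  curved <- trajectory(c(0, 5, -2, 3), c(0, 5, 7, 4), rep(0, 4))
  expect_equal(travelled_distance(curved), 5)
})

test_that("curve distances match their definitions on constant offsets", {
  set.seed(3)
  X <- random_traj(120)
  expect_equal(curve_distance(X, X), list(d_xy = 0, d_theta = 0))
  Y <- trajectory(X$x + 0.3, X$y + 0.4, X$theta, t = X$t)
  expect_equal(curve_distance(X, Y)$d_xy, 0.5, tolerance = 1e-12)
  expect_equal(curve_distance(X, Y)$d_theta, 0, tolerance = 1e-12)
  Z <- trajectory(X$x, X$y, X$theta + 0.2, t = X$t)
  expect_equal(curve_distance(X, Z)$d_xy, 0, tolerance = 1e-12)
  expect_equal(curve_distance(X, Z)$d_theta, 0.2, tolerance = 1e-12)
  short <- trajectory(1:10, 1:10, rep(0, 10))
  expect_error(curve_distance(X, short), "mismatched")
})

test_that("curve distance agrees with a per-sample brute-force oracle", {
  set.seed(7)
  for (k in 1:200) {
    A <- random_traj(40)
    B <- random_traj(40)
    # independent oracle: explicit loop over samples
    dxy <- 0; dth <- 0
    for (i in 1:40) {
      dxy <- dxy + sqrt((A$x[i] - B$x[i])^2 + (A$y[i] - B$y[i])^2)
      dth <- dth + abs(A$theta[i] - B$theta[i])
    }
    cd <- curve_distance(A, B)
    expect_equal(cd$d_xy, dxy / 40, tolerance = 1e-12)
    expect_equal(cd$d_theta, dth / 40, tolerance = 1e-12)
  }
})

test_that("d_xy is a pseudometric and rigid-motion invariant", {
  set.seed(11)
  for (k in 1:200) {
    A <- random_traj(30); B <- random_traj(30); C <- random_traj(30)
    dab <- curve_distance(A, B)$d_xy
    dba <- curve_distance(B, A)$d_xy
    dac <- curve_distance(A, C)$d_xy
    dcb <- curve_distance(C, B)$d_xy
    expect_equal(dab, dba, tolerance = 1e-9)
    expect_lte(dab, dac + dcb + 1e-9)
  }
  for (k in 1:50) {
    A <- random_traj(30); B <- random_traj(30)
    ang <- stats::runif(1, -pi, pi); tx <- stats::rnorm(1); ty <- stats::rnorm(1)
    d0 <- curve_distance(A, B)
    d1 <- curve_distance(rigid_move(A, ang, tx, ty), rigid_move(B, ang, tx, ty))
    expect_equal(d1$d_xy, d0$d_xy, tolerance = 1e-9)
    expect_equal(d1$d_theta, d0$d_theta, tolerance = 1e-9)
  }
})

test_that("trajectory averaging is the pointwise mean and refuses mixed cells", {
  set.seed(5)
  X <- random_traj(60)
  expect_equal(average_trajectory(list(X, X, X))$x, X$x, tolerance = 1e-12)

  A <- trajectory(rep(0, 10), rep(0, 10), rep(0, 10))
  B <- trajectory(rep(2, 10), rep(0, 10), rep(0, 10))
  M <- average_trajectory(list(A, B))
  expect_equal(M$x, rep(1, 10))

  expect_error(average_trajectory(list()), "empty")
  a <- X; attr(a, "config") <- "A"
  b <- X; attr(b, "config") <- "B"
  expect_error(average_trajectory(list(a, b)), "configurations")

  # the pointwise mean minimizes the summed squared deviations among
  # constant-shift candidates
  trajs <- lapply(1:6, function(i) random_traj(40))
  avg <- average_trajectory(trajs)
  sse <- function(ref) sum(vapply(trajs, function(tr)
    sum((tr$x - ref$x)^2 + (tr$y - ref$y)^2), 1))
  s0 <- sse(avg)
  for (k in 1:20) {
    shifted <- avg
    shifted$x <- avg$x + stats::rnorm(1, sd = 0.1)
    shifted$y <- avg$y + stats::rnorm(1, sd = 0.1)
    expect_gte(sse(shifted), s0)
  }
})

test_that("reversal is an involution and symmetry distances behave", {
  set.seed(9)
  X <- random_traj(80)
  expect_equal(reverse_trajectory(reverse_trajectory(X))$x, X$x, tolerance = 1e-12)
  expect_equal(reverse_trajectory(reverse_trajectory(X))$theta, X$theta,
               tolerance = 1e-12)
  const <- trajectory(rep(1, 10), rep(2, 10), rep(0.5, 10))
  expect_equal(reverse_trajectory(const)$x, const$x)
  ramp <- trajectory(seq(0, 1, length.out = 20), rep(0, 20), rep(0, 20))
  expect_equal(reverse_trajectory(ramp)$x, seq(1, 0, length.out = 20))

  ret <- reverse_trajectory(X)
  expect_equal(symmetry_distances(X, ret)$d_xy, 0, tolerance = 1e-12)
  ret_off <- trajectory(ret$x + 0.1, ret$y, ret$theta, t = ret$t)
  expect_equal(symmetry_distances(X, ret_off)$d_xy, 0.1, tolerance = 1e-12)
  unrelated <- trajectory(rep(9, 80), rep(9, 80), rep(0, 80))
  expect_gt(symmetry_distances(X, unrelated)$d_xy, 0)
})

test_that("configuration optimality compares per-subject and pair distances", {
  # derived comparison on constructed distances: A = (3, 5), B = (4, 3.5)
  oA <- copair:::optimality_from_distances(c(D1 = 3, D2 = 5), c(D1 = 4, D2 = 3.5), "A")
  oB <- copair:::optimality_from_distances(c(D1 = 3, D2 = 5), c(D1 = 4, D2 = 3.5), "B")
  expect_true(oA$optimal_for_subject1)
  expect_false(oA$optimal_for_subject2)
  expect_false(oA$optimal_for_pair)       # 8 > 7.5
  expect_true(oB$optimal_for_pair)
  expect_true(oB$optimal_for_subject2)
  expect_false(oB$optimal_for_subject1)

  # the tie goal: on-axis quarter-turn goal makes both configurations optimal
  goals <- make_goal_layout()
  tie <- classify_configuration_optimality(goals[[2]], "A")
  expect_true(tie$optimal_for_subject1 && tie$optimal_for_subject2 &&
              tie$optimal_for_pair)
  tieB <- classify_configuration_optimality(goals[[2]], "B")
  expect_true(tieB$optimal_for_pair)

  # choosing the unique pair-distance minimizer flags optimal_for_pair
  g <- goals[[4]]
  dA <- sum(copair:::subject_distances(g, "A"))
  dB <- sum(copair:::subject_distances(g, "B"))
  best <- if (dA < dB) "A" else "B"
  expect_true(classify_configuration_optimality(g, best)$optimal_for_pair)
})

test_that("trajectory JSON round-trips", {
  set.seed(2)
  X <- normalize_time(random_traj(40), 100)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_trajectory_json(X, path)
  Y <- read_trajectory_json(path)
  expect_equal(Y$x, X$x)
  expect_equal(Y$theta, X$theta)
  expect_equal(Y$entity, X$entity)
})
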