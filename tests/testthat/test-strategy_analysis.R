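# Strategy analysis battery: scenario comparisons, symmetry, optimality,
# variability, model assessment.

test_that("travel-time comparison summarizes cells and runs rank tests", {
  w <- reference_weights()
  des <- study_design(n_pairs = 10L, seed = 21L)
  ds <- generate_dataset(des, w, trajectories = FALSE)
  rep <- travel_time_comparison(ds)
  # scenario 1, 2, 3-forward, 3-return cells
  expect_setequal(rep$summary$cell,
                  c("scenario1", "scenario2", "scenario3.forward",
                    "scenario3.return"))
  expect_true(all(rep$pairwise$p >= 0 & rep$pairwise$p <= 1))
  expect_true(rep$omnibus_p >= 0 && rep$omnibus_p <= 1)
  # the design's scenario effect (shared knowledge speeds the task up) is
  # detectable at 10 pairs
  expect_lt(rep$omnibus_p, 0.05)
  expect_false(is.na(rep$shapiro_p))
})

test_that("scenario proximity votes follow the construction", {
  # scenario-3 paths copied from scenario 1 for subject 1 and from scenario 2
  # for subject 2: every vote is determined
  n <- 40
  trials <- list()
  for (pair in 1:2) for (goal in 1:3) {
    s1_a <- line_traj(c(0, 0), c(3, 0))
    s1_b <- line_traj(c(0, 0.6), c(3, 0.6))
    s2_a <- line_traj(c(1.8, 0), c(4.8, 0), theta = pi)
    s2_b <- line_traj(c(1.8, 0.6), c(4.8, 0.6), theta = pi)
    tab <- line_traj(c(0.9, 0), c(3.9, 0))
    trials <- c(trials, list(
      make_trial(pair, goal, 1, "forward", "A", 9, s1_a, s2_a, tab),
      make_trial(pair, goal, 2, "forward", "A", 9, s1_b, s2_b, tab),
      make_trial(pair, goal, 3, "forward", "A", 9, s1_a, s2_b, tab)))
  }
  rep <- scenario_path_proximity(as_dataset(trials))
  expect_equal(unname(rep$votes["subject1", "scenario1"]), 6L)
  expect_equal(unname(rep$votes["subject2", "scenario2"]), 6L)
  expect_equal(unname(rep$votes["subject1", "scenario2"]), 0L)
  expect_lt(rep$fisher_p, 0.05)
  # the distance table delegates to curve_distance: spot-check one trio
  one <- rep$distances[rep$distances$pair_id == 1 & rep$distances$goal_id == 1 &
                       rep$distances$entity == "subject1", ]
  expect_equal(one$d13, 0)
  expect_equal(one$d23, 0.6)
})

test_that("symmetry distances vanish for exact reversals and rank the table", {
  # forward/return pairs where the return is the exact reversed forward
  trials <- list()
  for (pair in 1:2) for (goal in 1:2) {
    s1 <- line_traj(c(0, 0), c(3, 1))
    s2 <- line_traj(c(1.8, 0), c(4.8, 1), theta = pi)
    tab <- line_traj(c(0.9, 0), c(3.9, 1))
    trials <- c(trials, list(
      make_trial(pair, goal, 3, "forward", "A", 9, s1, s2, tab),
      make_trial(pair, goal, 3, "return", "A", 9,
                 reverse_trajectory(s1), reverse_trajectory(s2),
                 reverse_trajectory(tab))))
  }
  # all-zero distances make the exact rank test degenerate (tied), hence
  # the suppressed ties warning
  rep <- suppressWarnings(symmetry_report(as_dataset(trials)))
  expect_equal(rep$summary$mean_d_xy, rep(0, 3), tolerance = 1e-12)
  expect_equal(nrow(rep$summary), 3L)       # 3 entities x 2 metrics

  # with the generator's noise, subject paths are less symmetrical than the
  # table's (its perturbation is smaller)
  w <- reference_weights()
  des <- study_design(n_pairs = 4L, seed = 13L)
  ds <- generate_dataset(des, w, base = "straight")
  repn <- symmetry_report(ds)
  s <- repn$summary
  expect_gt(s$mean_d_xy[s$entity == "subject1"], s$mean_d_xy[s$entity == "table"])
  expect_gt(s$mean_d_xy[s$entity == "subject2"], s$mean_d_xy[s$entity == "table"])
  expect_lt(repn$subject_vs_table_p[["subject1"]], 0.05)
})

test_that("variability vanishes without noise and tracks the noise level", {
  w <- reference_weights()
  des0 <- study_design(n_pairs = 3L, noise_xy = 0, noise_theta = 0, seed = 4L)
  ds0 <- generate_dataset(des0, w, base = "straight")
  # small cohorts leave some goal x config cells with one trial only
  v0 <- suppressWarnings(variability_report(ds0, des0$goals))
  expect_equal(max(v0$trial_distances$d_xy), 0, tolerance = 1e-9)

  des <- study_design(n_pairs = 5L, seed = 15L)
  ds <- generate_dataset(des, w, base = "straight")
  v <- suppressWarnings(variability_report(ds, des$goals))
  sub <- v$overall$mean_d_xy[v$overall$entity != "table"]
  tab <- v$overall$mean_d_xy[v$overall$entity == "table"]
  expect_true(all(sub > tab))
  expect_true(all(v$trial_distances$d_xy >= 0))
  # repeatability table covers pair x goal x entity with valid p-values
  expect_true(all(v$repeatability$p >= 0 & v$repeatability$p <= 1))
  # trend table: one row per goal x configuration actually observed
  expect_true(all(v$trend$global_distance >= 2.7 & v$trend$global_distance <= 5.4))
})

test_that("model assessment is self-consistent at the generating weights", {
  w <- reference_weights()
  goals <- make_goal_layout()
  lay <- data.frame(goal_id = c(1L, 4L), config = "A",
                    direction = c("forward", "return"))
  ds <- make_fit_dataset(w, goals, layout = lay, dt = 0.1)
  rep <- model_assessment(ds, w)
  expect_lt(max(rep$per_entry$d_xy), 0.01)
  expect_equal(rep$n_failed, 0L)

  # perturbed weights leave a strictly positive gap
  w2 <- cost_weights(w$alpha * rep(c(3, 0.3), length.out = 11),
                     w$beta * rep(c(3, 0.3), length.out = 4))
  rep2 <- model_assessment(ds, w2)
  expect_gt(mean(rep2$per_entry$d_xy), 0.005)
  # terminal miss is the euclidean distance at the last sample
  e1 <- rep$per_entry[1, ]
  sol <- solve_oc(ds$entries[[1]]$problem, w, n_out = 500)
  expect_equal(e1$miss_pos, unname(sol$terminal_error[["pos1"]]), tolerance = 1e-9)
})

test_that("percentage tables are consistent and p-values valid", {
  w <- reference_weights()
  des <- study_design(n_pairs = 6L, seed = 31L)
  ds <- generate_dataset(des, w, trajectories = FALSE)
  cfg <- configuration_optimality_rates(ds, des$goals)
  expect_true(all(cfg$rates$pct_optimal_pair >= 0 & cfg$rates$pct_optimal_pair <= 100))
  expect_true(all(cfg$rates$n == 6L * 9L))
  # policy 0.8 with one tie goal: expected pair-optimal rate
  # 100 * (8/9 * 0.8 + 1/9) across many trials
  expected <- 100 * (8 / 9 * 0.8 + 1 / 9)
  expect_lt(abs(mean(cfg$rates$pct_optimal_pair) - expected), 12)
})
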