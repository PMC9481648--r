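# Synthetic study-design generator: layout, trials, datasets, calibration.

test_that("the goal layout matches the study design constraints", {
  goals <- make_goal_layout()
  expect_length(goals, 9L)
  d <- vapply(goals, function(g) g$global_distance, 1)
  expect_true(all(d >= 2.7 & d <= 5.4))
  expect_gte(sum(vapply(goals, function(g) g$orientation_change, TRUE)), 3L)
  # the tie goal: equal per-subject distances under both configurations
  dA <- copair:::subject_distances(goals[[2]], "A")
  dB <- copair:::subject_distances(goals[[2]], "B")
  expect_equal(dA[["D1"]], dB[["D1"]], tolerance = 1e-9)
  expect_equal(dA[["D2"]], dB[["D2"]], tolerance = 1e-9)
})

test_that("the canonical IOC layout has 13 forward and 18 return entries", {
  lay <- ioc_default_layout()
  expect_equal(nrow(lay), 31L)
  expect_equal(sum(lay$direction == "forward"), 13L)
  expect_equal(sum(lay$direction == "return"), 18L)
})

test_that("trials are deterministic given the seed and regenerable in isolation", {
  w <- reference_weights()
  des <- study_design(seed = 3L)
  g <- des$goals[[3]]
  t1 <- generate_pair_trial(g, 2, "forward", w, des, pair_id = 4, base = "straight")
  t2 <- generate_pair_trial(g, 2, "forward", w, des, pair_id = 4, base = "straight")
  expect_identical(t1$subject1$x, t2$subject1$x)
  expect_identical(t1$travel_time, t2$travel_time)
  t3 <- generate_pair_trial(g, 2, "forward", w, des, pair_id = 5, base = "straight")
  expect_false(identical(t1$subject1$x, t3$subject1$x))
})

test_that("zero noise reproduces the base trajectories, endpoints always pinned", {
  w <- reference_weights()
  des0 <- study_design(noise_xy = 0, noise_theta = 0, seed = 2L)
  g <- des0$goals[[1]]
  tr <- generate_pair_trial(g, 3, "forward", w, des0, pair_id = 1, base = "oc")
  base <- copair:::base_trajectories(g, "A", "forward", w, base = "oc")
  expect_equal(tr$subject1$x, base$subject1$x, tolerance = 1e-12)
  expect_equal(tr$subject2$theta, base$subject2$theta, tolerance = 1e-12)

  des <- study_design(seed = 2L)
  trn <- generate_pair_trial(g, 3, "forward", w, des, pair_id = 1, base = "straight")
  basen <- copair:::base_trajectories(g, "A", "forward", w, base = "straight")
  for (ent in c("subject1", "subject2")) {
    n <- trn[[ent]]$n
    expect_equal(trn[[ent]]$x[c(1, n)], basen[[ent]]$x[c(1, n)], tolerance = 1e-12)
    expect_equal(trn[[ent]]$y[c(1, n)], basen[[ent]]$y[c(1, n)], tolerance = 1e-12)
    expect_equal(trn[[ent]]$theta[c(1, n)], basen[[ent]]$theta[c(1, n)],
                 tolerance = 1e-12)
  }
})

test_that("path noise is calibrated to the design's distance targets", {
  w <- reference_weights()
  des <- study_design(seed = 11L)
  g <- des$goals[[5]]
  base <- copair:::base_trajectories(g, "A", "forward", w, base = "straight")
  cache <- new.env()
  d <- vapply(1:50, function(r) {
    tr <- generate_pair_trial(g, 3, "forward", w, des, pair_id = 1, rep = r,
                              base = "straight", cache = cache)
    curve_distance(tr$subject1, base$subject1)$d_xy
  }, 1)
  expect_gte(mean(d), 0.16)
  expect_lte(mean(d), 0.24)
  dth <- vapply(1:20, function(r) {
    tr <- generate_pair_trial(g, 3, "forward", w, des, pair_id = 2, rep = r,
                              base = "straight", cache = cache)
    curve_distance(tr$subject1, base$subject1)$d_theta
  }, 1)
  expect_gte(mean(dth), 0.16)
  expect_lte(mean(dth), 0.24)
})

test_that("travel times follow the scenario laws with the 3 s floor", {
  des <- study_design(seed = 6L)
  set.seed(1)
  tts <- replicate(300, draw_travel_time(1, "forward", des))
  expect_true(all(tts >= 3))
  expect_equal(mean(tts), 9.6, tolerance = 0.05)
  # return paths use the shared-knowledge law
  set.seed(1)
  ttr <- replicate(300, draw_travel_time(1, "return", des))
  expect_equal(mean(ttr), 8.4, tolerance = 0.05)
})

test_that("a dataset is the full factorial of the design", {
  w <- reference_weights()
  des <- study_design(n_pairs = 2L, seed = 5L)
  ds <- generate_dataset(des, w, base = "straight")
  expect_length(ds, 2L * 9L * 3L * 2L)      # 54 per pair
  m <- dataset_manifest(ds)
  expect_equal(unname(table(m$pair_id)), rep(54L, 2L), ignore_attr = TRUE)
  # forward and return of the same pair x goal x scenario share a configuration
  sp <- split(m, list(m$pair_id, m$goal_id, m$scenario))
  expect_true(all(vapply(sp, function(z) length(unique(z$config)) == 1L, TRUE)))
  # the three returns per goal are the in-condition repeats
  rt <- m[m$direction == "return", ]
  reps <- split(rt$rep, list(rt$pair_id, rt$goal_id))
  expect_true(all(vapply(reps, function(r) all(sort(r) == 1:3), TRUE)))
  # metadata-only generation yields the same manifest skeleton
  ds_meta <- generate_dataset(des, w, trajectories = FALSE)
  m2 <- dataset_manifest(ds_meta)
  expect_equal(m2$config, m$config)
  expect_equal(m2$travel_time, m$travel_time)
})

test_that("the configuration policy drives pair-optimal choice rates", {
  w <- reference_weights()
  des_opt <- study_design(n_pairs = 3L, config_policy = 1, seed = 9L)
  ds <- generate_dataset(des_opt, w, trajectories = FALSE)
  rates <- configuration_optimality_rates(ds, des_opt$goals)
  expect_true(all(rates$rates$pct_optimal_pair == 100))
})
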