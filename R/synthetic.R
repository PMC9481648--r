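# Synthetic trial generator emulating the study design: 20 pairs, 9 goals,
# 3 scenarios, forward + return paths, smooth endpoint-pinned path noise.

#' Study design for the synthetic generator
#'
#' Encodes the experimental conditions the generator emulates: 20 pairs carry
#' a table to 9 goals (2.7-5.4 m away) under 3 scenarios (only Subject 1
#' knows the goal, only Subject 2 knows it, both know it), forward and return
#' paths. Travel times are scenario-dependent (leadership speeds the task
#' up); path-level variability about the underlying trajectory is ~0.20 m
#' linear and ~0.20 rad angular, with the table less variable than the
#' carriers.
#'
#' @param n_pairs number of pairs (default 20).
#' @param goals list of [goal_spec()] (default [make_goal_layout()]).
#' @param scenarios scenario subset of `1:3`.
#' @param base_travel_time per-scenario mean travel time (s),
#'   default `c(9.6, 8.9, 8.4)`.
#' @param travel_time_sd per-scenario travel-time standard deviation (s),
#'   default `c(2.2, 1.8, 1.5)`.
#' @param noise_xy target linear distance of a trial to its underlying path
#'   (m, default 0.20).
#' @param noise_theta target angular distance (rad, default 0.20).
#' @param table_noise_factor table perturbation relative to the carriers
#'   (default 0.75, matching the lower table variability).
#' @param config_policy probability that a forward trial picks a
#'   pair-optimal configuration (default 0.8); ties are split uniformly.
#' @param seed master seed; every trial hashes it with its coordinates so any
#'   trial is regenerable in isolation.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_pairs = 20L, goals = make_goal_layout(),
                         scenarios = 1:3,
                         base_travel_time = c(9.6, 8.9, 8.4),
                         travel_time_sd = c(2.2, 1.8, 1.5),
                         noise_xy = 0.20, noise_theta = 0.20,
                         table_noise_factor = 0.75,
                         config_policy = 0.8, seed = 1L) {
  stopifnot(n_pairs >= 1L, noise_xy >= 0, noise_theta >= 0,
            config_policy >= 0, config_policy <= 1)
  d <- vapply(goals, function(g) g$global_distance, 1)
  if (any(d < 2.7 - 1e-6 | d > 5.4 + 1e-6))
    stop("goal global distances must lie in [2.7, 5.4] m", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs), goals = goals,
                 scenarios = scenarios,
                 base_travel_time = base_travel_time,
                 travel_time_sd = travel_time_sd,
                 noise_xy = noise_xy, noise_theta = noise_theta,
                 table_noise_factor = table_noise_factor,
                 config_policy = config_policy, seed = as.integer(seed)),
            class = "study_design")
}

#' Draw a travel time
#'
#' Normal draw from the scenario's law, truncated below at 3 s (redrawn).
#' Return paths always use the Scenario-3 law: on the way back both carriers
#' know the destination regardless of the outbound scenario.
#'
#' @param scenario 1, 2 or 3.
#' @param direction `"forward"` or `"return"`.
#' @param design a [study_design()].
#' @return travel time (s).
#' @export
draw_travel_time <- function(scenario, direction, design) {
  k <- if (direction == "return") 3L else as.integer(scenario)
  repeat {
    tt <- stats::rnorm(1L, design$base_travel_time[k], design$travel_time_sd[k])
    if (tt >= 3) return(tt)
  }
}

# Endpoint-pinned smooth perturbation: a sum of 3-6 low-frequency sinusoids
# sin(pi k tau) per coordinate (zero at both ends), scaled so the realized
# linear / angular distance to the pinned base equals exactly noise_xy /
# noise_theta.
smooth_perturbation <- function(n, noise_xy, noise_theta) {
  tau <- seq(0, 1, length.out = n)
  draw <- function() {
    K <- sample(3:6, 1L)
    amp <- stats::rnorm(K) / seq_len(K)      # low frequencies dominate
    as.vector(sin(pi * outer(tau, seq_len(K))) %*% amp)
  }
  ex <- draw(); ey <- draw(); eth <- draw()
  if (noise_xy > 0) {
    dxy <- mean(sqrt(ex^2 + ey^2))
    if (dxy > 0) { ex <- ex * noise_xy / dxy; ey <- ey * noise_xy / dxy }
  } else { ex <- ex * 0; ey <- ey * 0 }
  if (noise_theta > 0) {
    dth <- mean(abs(eth))
    if (dth > 0) eth <- eth * noise_theta / dth
  } else eth <- eth * 0
  list(x = ex, y = ey, theta = eth)
}

# swap the subject slots of an OC problem (role switch)
switch_problem <- function(p) {
  p$x_s <- c(p$x_s[7:12], p$x_s[1:6])
  p$x_f <- c(p$x_f[4:6], p$x_f[1:3])
  p
}

# Base (noise-free) subject trajectories for one goal/config/direction.
# Return paths embody the role-switch hypothesis: the model is solved with
# the subject slots exchanged (the carrier facing the destination leads) and
# the outputs are relabelled back.
base_trajectories <- function(goal, config, direction, weights,
                              base = c("oc", "straight"), n_out = 500L,
                              dt = 0.05) {
  base <- match.arg(base)
  problem <- goal_problem(goal, config = config, direction = direction, dt = dt)
  switched <- direction == "return"
  if (switched) problem <- switch_problem(problem)
  if (base == "oc") {
    sol <- solve_oc(problem, weights, n_out = n_out)
    s1 <- sol$subject1; s2 <- sol$subject2
  } else {
    ws <- warm_start(problem)
    t_raw <- seq(0, problem$T, length.out = nrow(ws$X))
    s1 <- normalize_time(trajectory(ws$X[, 1L], ws$X[, 2L], ws$X[, 3L],
                                    t = t_raw, entity = "subject1",
                                    normalized = FALSE), n_out)
    s2 <- normalize_time(trajectory(ws$X[, 7L], ws$X[, 8L], ws$X[, 9L],
                                    t = t_raw, entity = "subject2",
                                    normalized = FALSE), n_out)
  }
  if (switched) {
    tmp <- s1
    s1 <- s2; s1$entity <- "subject1"
    s2 <- tmp; s2$entity <- "subject2"
  }
  list(subject1 = s1, subject2 = s2)
}

#' Generate one synthetic carriage trial
#'
#' The underlying paths are the coupled OC model's solution for the goal
#' (cached across trials); each carrier's measured path is the base plus a
#' smooth endpoint-pinned random perturbation scaled to the design's noise
#' levels. The table path is the midpoint of the carriers' base grip points
#' with its own smaller perturbation, and its heading points from carrier 1
#' to carrier 2. The travel time is drawn from the scenario's truncated
#' normal law. A trial is fully determined by the design seed and its
#' coordinates.
#'
#' @param goal a [goal_spec()].
#' @param scenario 1, 2 or 3.
#' @param direction `"forward"` or `"return"`.
#' @param weights a [cost_weights()] for the base model.
#' @param design a [study_design()].
#' @param pair_id pair index.
#' @param config table configuration `"A"` or `"B"`.
#' @param rep repetition index (used only in the trial seed).
#' @param base `"oc"` (default, the study condition) or `"straight"` (warm
#'   start paths; a fast stand-in used where only counts or noise structure
#'   matter).
#' @param cache optional environment caching base trajectories across trials.
#' @param n_out samples per normalized trajectory (default 500).
#' @return a `trial_record` list: metadata plus three normalized
#'   trajectories (`subject1`, `subject2`, `table`).
#' @export
generate_pair_trial <- function(goal, scenario, direction, weights, design,
                                pair_id, config = "A", rep = 1L,
                                base = c("oc", "straight"), cache = NULL,
                                n_out = 500L) {
  base <- match.arg(base)
  dir_code <- if (direction == "forward") 1L else 2L
  cfg_code <- if (config == "A") 1L else 2L
  set.seed(hash_seed(design$seed, pair_id, goal$goal_id, scenario, dir_code,
                     cfg_code, rep))
  tt <- draw_travel_time(scenario, direction, design)
  key <- sprintf("g%d_%s_%s_%s", goal$goal_id, config, direction, base)
  bt <- if (!is.null(cache)) cache[[key]] else NULL
  if (is.null(bt)) {
    bt <- base_trajectories(goal, config, direction, weights, base = base,
                            n_out = n_out)
    if (!is.null(cache)) cache[[key]] <- bt
  }
  perturb <- function(tr, fac = 1) {
    p <- smooth_perturbation(tr$n, design$noise_xy * fac, design$noise_theta * fac)
    trajectory(tr$x + p$x, tr$y + p$y, tr$theta + p$theta, t = tr$t,
               entity = tr$entity, normalized = TRUE)
  }
  s1 <- perturb(bt$subject1)
  s2 <- perturb(bt$subject2)
  tab_base <- trajectory((bt$subject1$x + bt$subject2$x) / 2,
                         (bt$subject1$y + bt$subject2$y) / 2,
                         atan2(bt$subject2$y - bt$subject1$y,
                               bt$subject2$x - bt$subject1$x),
                         t = bt$subject1$t, entity = "table", normalized = TRUE)
  tab <- perturb(tab_base, design$table_noise_factor)
  out <- list(pair_id = pair_id, goal_id = goal$goal_id, scenario = scenario,
              direction = direction, config = config, rep = rep,
              travel_time = tt,
              subject1 = s1, subject2 = s2, table = tab)
  attr(out$subject1, "config") <- config
  attr(out$subject2, "config") <- config
  attr(out$table, "config") <- config
  structure(out, class = "trial_record")
}

#' Generate a full synthetic dataset
#'
#' Full factorial of pairs x goals x scenarios x directions (54 trials per
#' pair with the default design; the three returns from each goal are the
#' in-condition repeats, since return paths always run under Scenario-3
#' knowledge). The configuration of each forward trial is drawn from the
#' design's configuration policy and reused for the matching return.
#'
#' @param design a [study_design()].
#' @param weights a [cost_weights()] for the base model.
#' @param base `"oc"` (default) or `"straight"`, see [generate_pair_trial()].
#' @param trajectories if `FALSE`, only metadata (configuration, travel time)
#'   is generated -- used for travel-time and configuration statistics where
#'   paths are not needed.
#' @return a list of `trial_record`s with class `trial_dataset`; the design
#'   is attached as an attribute.
#' @export
generate_dataset <- function(design, weights = reference_weights(),
                             base = c("oc", "straight"), trajectories = TRUE) {
  stopifnot(inherits(design, "study_design"))
  base <- match.arg(base)
  cache <- new.env(parent = emptyenv())
  trials <- list()
  for (pair_id in seq_len(design$n_pairs)) {
    for (goal in design$goals) {
      n_return <- 0L
      for (scenario in design$scenarios) {
        set.seed(hash_seed(design$seed, pair_id, goal$goal_id, scenario, 0L))
        config <- choose_config(goal, design$config_policy)
        for (direction in c("forward", "return")) {
          n_return <- n_return + (direction == "return")
          rep <- if (direction == "return") n_return else 1L
          if (trajectories) {
            tr <- generate_pair_trial(goal, scenario, direction, weights,
                                      design, pair_id, config = config,
                                      rep = rep, base = base, cache = cache)
          } else {
            set.seed(hash_seed(design$seed, pair_id, goal$goal_id, scenario,
                               if (direction == "forward") 1L else 2L,
                               if (config == "A") 1L else 2L, rep))
            tr <- structure(list(pair_id = pair_id, goal_id = goal$goal_id,
                                 scenario = scenario, direction = direction,
                                 config = config, rep = rep,
                                 travel_time = draw_travel_time(scenario,
                                                                direction, design),
                                 subject1 = NULL, subject2 = NULL, table = NULL),
                            class = "trial_record")
          }
          trials[[length(trials) + 1L]] <- tr
        }
      }
    }
  }
  structure(trials, class = "trial_dataset", design = design)
}

# draw a configuration: pair-optimal with probability `policy`; uniform on tie
choose_config <- function(goal, policy) {
  lab_A <- classify_configuration_optimality(goal, "A")
  if (lab_A$optimal_for_pair &&
      classify_configuration_optimality(goal, "B")$optimal_for_pair) {
    return(sample(c("A", "B"), 1L))                 # tie goal
  }
  pair_opt <- if (lab_A$optimal_for_pair) "A" else "B"
  other <- setdiff(c("A", "B"), pair_opt)
  if (stats::runif(1L) < policy) pair_opt else other
}

#' Manifest of a trial dataset
#'
#' @param dataset a [generate_dataset()] result.
#' @return a data frame with one row per trial: pair, goal, scenario,
#'   direction, configuration, repetition, travel time.
#' @export
dataset_manifest <- function(dataset) {
  f <- function(field, proto) vapply(dataset, function(tr) as.vector(tr[[field]], mode = mode(proto)), proto)
  data.frame(idx = seq_along(dataset),
             pair_id = f("pair_id", 1), goal_id = f("goal_id", 1),
             scenario = f("scenario", 1), direction = f("direction", ""),
             config = f("config", ""), rep = f("rep", 1),
             travel_time = f("travel_time", 1))
}

#' Canonical IOC entry layout
#'
#' The Scenario-3 fitting dataset layout: forward paths in one configuration
#' for the five translation goals and in both configurations for the four
#' quarter-turn goals (13 forward entries -- the table was not always laid the
#' same way), and return paths in both configurations for all nine goals
#' (18 return entries), 31 entries in total.
#'
#' @param goals list of [goal_spec()] (default [make_goal_layout()]).
#' @return data frame with columns `goal_id`, `config`, `direction`.
#' @export
ioc_default_layout <- function(goals = make_goal_layout()) {
  rows <- list()
  for (g in goals) {
    both <- g$orientation_change ||
      (classify_configuration_optimality(g, "A")$optimal_for_pair &&
       classify_configuration_optimality(g, "B")$optimal_for_pair)
    fw_cfg <- if (both) c("A", "B") else {
      if (classify_configuration_optimality(g, "A")$optimal_for_pair) "A" else "B"
    }
    for (cfg in fw_cfg)
      rows[[length(rows) + 1L]] <- data.frame(goal_id = g$goal_id, config = cfg,
                                              direction = "forward")
    for (cfg in c("A", "B"))
      rows[[length(rows) + 1L]] <- data.frame(goal_id = g$goal_id, config = cfg,
                                              direction = "return")
  }
  do.call(rbind, rows)
}

#' Build an IOC fitting dataset from the OC model
#'
#' Generates the average trajectories of each layout entry directly from the
#' coupled OC model at the given weights (noiseless averages: with the
#' default layout this is the 31-entry Scenario-3 fitting set). Used for
#' parameter-recovery studies and model assessment.
#'
#' @param weights a [cost_weights()] generating the averages.
#' @param goals list of [goal_spec()].
#' @param layout entry layout (default [ioc_default_layout()]); a data frame
#'   with `goal_id`, `config`, `direction`.
#' @param dt integration step for the entry problems (s).
#' @param n_out samples per trajectory.
#' @return a [fit_dataset()].
#' @export
make_fit_dataset <- function(weights, goals = make_goal_layout(),
                             layout = ioc_default_layout(goals),
                             dt = 0.05, n_out = 500L) {
  entries <- lapply(seq_len(nrow(layout)), function(i) {
    g <- goals[[layout$goal_id[i]]]
    problem <- goal_problem(g, config = layout$config[i],
                            direction = layout$direction[i], dt = dt)
    bt <- base_trajectories(g, layout$config[i], layout$direction[i], weights,
                            base = "oc", n_out = n_out, dt = dt)
    fit_entry(problem, bt$subject1, bt$subject2,
              direction = layout$direction[i],
              goal_id = g$goal_id, config = layout$config[i])
  })
  fit_dataset(entries)
}
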