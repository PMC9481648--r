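# Strategy analysis battery over a trial dataset: scenario comparisons,
# forward/return symmetry, configuration optimality, variability and model
# assessment. All inference is non-parametric (rank and exact tests), gated
# by a Shapiro-Wilk normality check.

entities <- c("subject1", "subject2", "table")

# Shapiro-Wilk gate: records whether the data look normal; the pipeline uses
# rank/exact tests downstream either way (they stay valid under normality).
normality_gate <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) return(NA_real_)
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  if (stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' Travel-time comparison across scenarios
#'
#' Summarizes travel times (mean +/- sd) per scenario with a forward/return
#' split for Scenario 3, runs a Kruskal-Wallis omnibus rank test across
#' scenarios on the forward paths, pairwise Mann-Whitney tests, and a
#' Mann-Whitney test of Scenario-3 forward times against all return times.
#'
#' @param dataset a [generate_dataset()] result (trajectories not required).
#' @return a list of class `travel_time_report`: `summary` (per
#'   scenario x direction cell), `omnibus_p`, `pairwise` (data frame),
#'   `forward_vs_return_p`, `shapiro_p`.
#' @export
travel_time_comparison <- function(dataset) {
  m <- dataset_manifest(dataset)
  fw <- m[m$direction == "forward", ]
  counts <- table(fw$scenario)
  keep <- as.integer(names(counts)[counts >= 2L])
  dropped <- setdiff(unique(fw$scenario), keep)
  if (length(dropped) > 0L)
    warning(sprintf("scenario(s) %s excluded from tests: fewer than 2 forward trials",
                    paste(dropped, collapse = ", ")))
  if (length(keep) < 2L) stop("need at least 2 scenarios to compare", call. = FALSE)
  cell <- m
  cell$cell <- ifelse(cell$scenario == 3L & cell$direction == "return",
                      "scenario3.return",
                      ifelse(cell$scenario == 3L, "scenario3.forward",
                             paste0("scenario", cell$scenario)))
  cell <- cell[cell$direction == "forward" | cell$scenario == 3L, ]
  summ <- do.call(rbind, lapply(split(cell, cell$cell), function(d)
    data.frame(cell = d$cell[1L], n = nrow(d),
               mean_s = mean(d$travel_time), sd_s = stats::sd(d$travel_time))))
  rownames(summ) <- NULL
  fw_t <- fw[fw$scenario %in% keep, ]
  omni <- stats::kruskal.test(fw_t$travel_time, factor(fw_t$scenario))$p.value
  pairs <- utils::combn(keep, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    data.frame(scenario_a = a, scenario_b = b,
               p = stats::wilcox.test(fw$travel_time[fw$scenario == a],
                                      fw$travel_time[fw$scenario == b])$p.value)
  }))
  pw$p_bh <- stats::p.adjust(pw$p, "BH")   # extension: the raw p is primary
  rt <- m$travel_time[m$direction == "return"]
  f3 <- fw$travel_time[fw$scenario == 3L]
  fvr <- if (length(rt) >= 2L && length(f3) >= 2L)
    stats::wilcox.test(f3, rt)$p.value else NA_real_
  structure(list(summary = summ, omnibus_p = omni, pairwise = pw,
                 forward_vs_return_p = fvr,
                 shapiro_p = normality_gate(m$travel_time)),
            class = "travel_time_report")
}

# fetch the trajectory of one entity from a trial
trial_traj <- function(trial, entity) trial[[entity]]

#' Scenario path proximity (which lone-leader path does the shared path follow?)
#'
#' For every pair x goal whose three forward trials ended in the same table
#' configuration, computes the linear distances between the scenario paths
#' (1-3, 2-3, 1-2) per entity, votes for the lone-leader scenario whose path
#' is nearer the Scenario-3 path, and tests the vote x subject contingency
#' with Fisher's exact test (one vote per pair x goal).
#'
#' @param dataset a [generate_dataset()] result with trajectories.
#' @return list of class `proximity_report`: `distances` (tidy data frame),
#'   `votes` (2x2 contingency subject x nearest scenario), `fisher_p`,
#'   `n_skipped` (pair x goal trios without a shared configuration).
#' @export
scenario_path_proximity <- function(dataset) {
  m <- dataset_manifest(dataset)
  fw <- m[m$direction == "forward", ]
  rows <- list(); votes <- list()
  n_skipped <- 0L
  for (pg in split(fw, list(fw$pair_id, fw$goal_id), drop = TRUE)) {
    if (!all(1:3 %in% pg$scenario)) { n_skipped <- n_skipped + 1L; next }
    if (length(unique(pg$config)) != 1L) { n_skipped <- n_skipped + 1L; next }
    idx <- vapply(1:3, function(s) pg$idx[pg$scenario == s][1L], 1L)
    for (ent in entities) {
      t1 <- trial_traj(dataset[[idx[1L]]], ent)
      t2 <- trial_traj(dataset[[idx[2L]]], ent)
      t3 <- trial_traj(dataset[[idx[3L]]], ent)
      d13 <- curve_distance(t1, t3)$d_xy
      d23 <- curve_distance(t2, t3)$d_xy
      d12 <- curve_distance(t1, t2)$d_xy
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pg$pair_id[1L], goal_id = pg$goal_id[1L], entity = ent,
        d13 = d13, d23 = d23, d12 = d12)
      if (ent != "table")
        votes[[length(votes) + 1L]] <- data.frame(
          subject = ent, nearest = if (d13 < d23) "scenario1" else "scenario2")
    }
  }
  if (length(rows) == 0L) stop("no comparable scenario trios found", call. = FALSE)
  v <- do.call(rbind, votes)
  tab <- table(factor(v$subject, c("subject1", "subject2")),
               factor(v$nearest, c("scenario1", "scenario2")))
  structure(list(distances = do.call(rbind, rows), votes = tab,
                 fisher_p = stats::fisher.test(tab)$p.value,
                 n_skipped = n_skipped),
            class = "proximity_report")
}

#' Configuration optimality rates
#'
#' For every forward trial, classifies the chosen table configuration as
#' optimal or not for Subject 1, Subject 2 and the pair (straight-line
#' travelled distances over the two configurations; ties count as optimal
#' for both) and reports the percentage of optimal choices per scenario. A
#' Fisher exact test checks whether pair-optimal choices are distributed
#' non-randomly across scenarios.
#'
#' @param dataset a [generate_dataset()] result (trajectories not required).
#' @param goals the goal layout the dataset was generated with.
#' @return list of class `config_report`: `rates` (per scenario, percent),
#'   `per_trial` flags, `fisher_p`.
#' @export
configuration_optimality_rates <- function(dataset, goals = make_goal_layout()) {
  m <- dataset_manifest(dataset)
  fw <- m[m$direction == "forward", ]
  flags <- do.call(rbind, lapply(seq_len(nrow(fw)), function(i) {
    lab <- classify_configuration_optimality(goals[[fw$goal_id[i]]],
                                             fw$config[i])
    data.frame(pair_id = fw$pair_id[i], goal_id = fw$goal_id[i],
               scenario = fw$scenario[i], config = fw$config[i],
               opt_s1 = lab$optimal_for_subject1,
               opt_s2 = lab$optimal_for_subject2,
               opt_pair = lab$optimal_for_pair)
  }))
  rates <- do.call(rbind, lapply(split(flags, flags$scenario), function(d)
    data.frame(scenario = d$scenario[1L], n = nrow(d),
               pct_optimal_subject1 = 100 * mean(d$opt_s1),
               pct_optimal_subject2 = 100 * mean(d$opt_s2),
               pct_optimal_pair = 100 * mean(d$opt_pair))))
  rownames(rates) <- NULL
  tab <- table(flags$scenario, flags$opt_pair)
  fisher_p <- if (all(dim(tab) == c(length(unique(flags$scenario)), 2L)) &&
                  nrow(tab) >= 2L)
    stats::fisher.test(tab)$p.value else NA_real_
  structure(list(rates = rates, per_trial = flags, fisher_p = fisher_p),
            class = "config_report")
}

#' Forward/return symmetry report
#'
#' Matches each forward trial with the return trial of the same
#' pair x goal x scenario and computes the linear and angular distances
#' between the forward path and the reversed return path per entity. Smaller
#' distances mean more symmetrical paths. A Mann-Whitney test compares each
#' subject's linear symmetry distances with the table's.
#'
#' @param dataset a [generate_dataset()] result with trajectories.
#' @return list of class `symmetry_report`: `distances` (tidy), `summary`
#'   (3 entity rows x 2 metrics), `subject_vs_table_p` (named vector).
#' @export
symmetry_report <- function(dataset) {
  m <- dataset_manifest(dataset)
  rows <- list()
  key <- function(d) paste(d$pair_id, d$goal_id, d$scenario)
  fw <- m[m$direction == "forward", ]
  rt <- m[m$direction == "return", ]
  rt_idx <- stats::setNames(rt$idx, key(rt))
  for (i in seq_len(nrow(fw))) {
    j <- rt_idx[key(fw[i, ])]
    if (is.na(j)) next
    for (ent in entities) {
      sd <- symmetry_distances(trial_traj(dataset[[fw$idx[i]]], ent),
                               trial_traj(dataset[[j]], ent))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = fw$pair_id[i], goal_id = fw$goal_id[i],
        scenario = fw$scenario[i], entity = ent,
        d_xy = sd$d_xy, d_theta = sd$d_theta)
    }
  }
  if (length(rows) == 0L) stop("no matched forward/return trials", call. = FALSE)
  d <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(d, d$entity), function(z)
    data.frame(entity = z$entity[1L], n = nrow(z),
               mean_d_xy = mean(z$d_xy), sd_d_xy = stats::sd(z$d_xy),
               mean_d_theta = mean(z$d_theta), sd_d_theta = stats::sd(z$d_theta))))
  rownames(summ) <- NULL
  p <- c(
    subject1 = stats::wilcox.test(d$d_xy[d$entity == "subject1"],
                                  d$d_xy[d$entity == "table"])$p.value,
    subject2 = stats::wilcox.test(d$d_xy[d$entity == "subject2"],
                                  d$d_xy[d$entity == "table"])$p.value)
  structure(list(distances = d, summary = summ, subject_vs_table_p = p,
                 shapiro_p = normality_gate(d$d_xy)),
            class = "symmetry_report")
}

#' Variability report: distances to the average trajectory
#'
#' Cells are defined as goal x configuration x scenario x direction
#' (averaging never crosses configurations). For every cell with at least two
#' trials, the average trajectory is computed per entity and each trial's
#' linear/angular distance to it is recorded. The report adds per-scenario
#' summaries, the within-pair repeatability of the three returns per goal
#' (Kruskal-Wallis over the three repeats' per-sample deviations from their
#' own average), and the trend of mean distance versus global distance with
#' the orientation-change flag.
#'
#' @param dataset a [generate_dataset()] result with trajectories.
#' @param goals the goal layout.
#' @return list of class `variability_report`: `trial_distances`, `summary`
#'   (per scenario x entity), `overall` (per entity), `repeatability`
#'   (per pair x goal x entity p-values), `trend` (per goal x config),
#'   `n_singleton` (skipped cells).
#' @export
variability_report <- function(dataset, goals = make_goal_layout()) {
  m <- dataset_manifest(dataset)
  rows <- list()
  n_singleton <- 0L
  for (cell in split(m, list(m$goal_id, m$config, m$scenario, m$direction),
                     drop = TRUE)) {
    if (nrow(cell) < 2L) { n_singleton <- n_singleton + 1L; next }
    for (ent in entities) {
      trajs <- lapply(cell$idx, function(i) trial_traj(dataset[[i]], ent))
      avg <- average_trajectory(trajs)
      for (r in seq_len(nrow(cell))) {
        cd <- curve_distance(trajs[[r]], avg)
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = cell$pair_id[r], goal_id = cell$goal_id[r],
          scenario = cell$scenario[r], direction = cell$direction[r],
          config = cell$config[r], entity = ent,
          d_xy = cd$d_xy, d_theta = cd$d_theta)
      }
    }
  }
  if (n_singleton > 0L)
    warning(sprintf("%d singleton cell(s) skipped", n_singleton))
  if (length(rows) == 0L) stop("no cell with at least 2 trials", call. = FALSE)
  d <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(d, list(d$scenario, d$entity)), function(z)
    data.frame(scenario = z$scenario[1L], entity = z$entity[1L], n = nrow(z),
               mean_d_xy = mean(z$d_xy), sd_d_xy = stats::sd(z$d_xy),
               mean_d_theta = mean(z$d_theta), sd_d_theta = stats::sd(z$d_theta))))
  rownames(summ) <- NULL
  overall <- do.call(rbind, lapply(split(d, d$entity), function(z)
    data.frame(entity = z$entity[1L],
               mean_d_xy = mean(z$d_xy), sd_d_xy = stats::sd(z$d_xy),
               mean_d_theta = mean(z$d_theta), sd_d_theta = stats::sd(z$d_theta))))
  rownames(overall) <- NULL
  # within-pair repeatability of the 3 returns per goal
  rep_rows <- list()
  rt <- m[m$direction == "return", ]
  for (pg in split(rt, list(rt$pair_id, rt$goal_id), drop = TRUE)) {
    if (nrow(pg) < 3L || length(unique(pg$config)) != 1L) next
    for (ent in entities) {
      trajs <- lapply(pg$idx, function(i) trial_traj(dataset[[i]], ent))
      avg <- average_trajectory(trajs)
      dev <- lapply(trajs, function(tr)
        sqrt((tr$x - avg$x)^2 + (tr$y - avg$y)^2))
      grp <- rep(seq_along(dev), each = length(dev[[1L]]))
      p <- stats::kruskal.test(unlist(dev), factor(grp))$p.value
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        pair_id = pg$pair_id[1L], goal_id = pg$goal_id[1L], entity = ent, p = p)
    }
  }
  repeatability <- if (length(rep_rows) > 0L) do.call(rbind, rep_rows) else NULL
  gd <- stats::setNames(vapply(goals, function(g) g$global_distance, 1),
                        vapply(goals, function(g) g$goal_id, 1L))
  oc_flag <- stats::setNames(vapply(goals, function(g) g$orientation_change, TRUE),
                             vapply(goals, function(g) g$goal_id, 1L))
  sub <- d[d$entity != "table", ]
  trend <- do.call(rbind, lapply(split(sub, list(sub$goal_id, sub$config),
                                       drop = TRUE), function(z)
    data.frame(goal_id = z$goal_id[1L], config = z$config[1L],
               global_distance = gd[[as.character(z$goal_id[1L])]],
               orientation_change = oc_flag[[as.character(z$goal_id[1L])]],
               mean_d_xy = mean(z$d_xy))))
  rownames(trend) <- NULL
  structure(list(trial_distances = d, summary = summ, overall = overall,
                 repeatability = repeatability, trend = trend,
                 n_singleton = n_singleton,
                 shapiro_p = normality_gate(d$d_xy)),
            class = "variability_report")
}

#' Model assessment against average trajectories
#'
#' For every entry of a fitting dataset, solves the coupled OC model at the
#' given weights (with the return-path role switch) and reports the linear
#' and angular distances between the generated and the average trajectories,
#' split by subject and direction, plus the terminal goal misses (position
#' and angle at the last sample). If reference distances (e.g. the
#' trial-to-average distances of [variability_report()]) are supplied, a
#' Mann-Whitney test compares the model-to-average gap with the measured
#' variability.
#'
#' @param dataset_averages a [fit_dataset()].
#' @param weights a [cost_weights()].
#' @param reference_d_xy optional numeric vector of trial-to-average linear
#'   distances to compare against.
#' @param solver_options list passed to [solve_oc()].
#' @return list of class `assessment_report`: `per_entry`, `by_direction`
#'   summaries, `terminal`, `gap_p`.
#' @export
model_assessment <- function(dataset_averages, weights, reference_d_xy = NULL,
                             solver_options = list()) {
  stopifnot(inherits(dataset_averages, "fit_dataset"))
  entries <- lapply(dataset_averages$entries, role_switch_return)
  rows <- list()
  for (j in seq_along(entries)) {
    e <- entries[[j]]
    args <- c(list(problem = e$problem, weights = weights, n_out = e$avg1$n),
              solver_options)
    sol <- tryCatch(do.call(solve_oc, args), error = function(err) NULL)
    if (is.null(sol)) {
      rows[[length(rows) + 1L]] <- data.frame(
        entry = j, goal_id = e$goal_id, direction = e$direction,
        subject = NA, d_xy = NA, d_theta = NA, miss_pos = NA, miss_ang = NA,
        failed = TRUE)
      next
    }
    for (s in 1:2) {
      cd <- curve_distance(e[[paste0("avg", s)]], sol[[paste0("subject", s)]])
      rows[[length(rows) + 1L]] <- data.frame(
        entry = j, goal_id = e$goal_id, direction = e$direction,
        subject = s, d_xy = cd$d_xy, d_theta = cd$d_theta,
        miss_pos = unname(sol$terminal_error[[paste0("pos", s)]]),
        miss_ang = unname(sol$terminal_error[[paste0("ang", s)]]),
        failed = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  ok <- per[!per$failed, ]
  by_dir <- do.call(rbind, lapply(split(ok, ok$direction), function(z)
    data.frame(direction = z$direction[1L], n = nrow(z),
               mean_d_xy = mean(z$d_xy), sd_d_xy = stats::sd(z$d_xy),
               mean_d_theta = mean(z$d_theta), sd_d_theta = stats::sd(z$d_theta),
               mean_miss_pos = mean(z$miss_pos), mean_miss_ang = mean(z$miss_ang))))
  rownames(by_dir) <- NULL
  gap_p <- if (!is.null(reference_d_xy) && nrow(ok) >= 2L)
    stats::wilcox.test(ok$d_xy, reference_d_xy)$p.value else NA_real_
  structure(list(per_entry = per, by_direction = by_dir,
                 terminal = ok[, c("entry", "goal_id", "direction", "subject",
                                   "miss_pos", "miss_ang")],
                 gap_p = gap_p, n_failed = sum(per$failed)),
            class = "assessment_report")
}
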