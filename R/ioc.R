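# Bi-level inverse optimal control: recover cost weights whose OC solutions
# best fit a set of average trajectories.

#' One entry of an IOC fitting dataset
#'
#' @param problem an [oc_problem()] with a numeric horizon (the start/goal the
#'   averaged trials shared).
#' @param avg1,avg2 average trajectories of Subject 1 and Subject 2,
#'   normalized to the same sample count.
#' @param direction `"forward"` or `"return"`.
#' @param goal_id,config metadata carried along.
#' @return an object of class `fit_entry`.
#' @export
fit_entry <- function(problem, avg1, avg2, direction = c("forward", "return"),
                      goal_id = NA_integer_, config = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(inherits(problem, "oc_problem"),
            inherits(avg1, "copair_traj"), inherits(avg2, "copair_traj"))
  if (avg1$n != avg2$n) stop("average trajectories must share N", call. = FALSE)
  structure(list(problem = problem, avg1 = avg1, avg2 = avg2,
                 direction = direction, goal_id = goal_id, config = config),
            class = "fit_entry")
}

#' IOC fitting dataset
#'
#' @param entries non-empty list of [fit_entry()] objects, all with the same
#'   trajectory sample count.
#' @return an object of class `fit_dataset`.
#' @export
fit_dataset <- function(entries) {
  if (length(entries) == 0L) stop("fit dataset must be nonempty", call. = FALSE)
  stopifnot(all(vapply(entries, inherits, TRUE, "fit_entry")))
  ns <- vapply(entries, function(e) e$avg1$n, 1L)
  if (length(unique(ns)) != 1L)
    stop("all entries must share the trajectory sample count", call. = FALSE)
  structure(list(entries = entries, n_traj = length(entries)),
            class = "fit_dataset")
}

#' Swap subject roles on a return-path entry
#'
#' On the way back the carrier who walked forward now walks backward; the
#' fitting convention assumes Subject 1 becomes Subject 2 and conversely on
#' return paths. Forward entries pass through unchanged; applying the switch
#' twice is the identity.
#'
#' @param entry a [fit_entry()].
#' @return the (possibly role-switched) entry.
#' @export
role_switch_return <- function(entry) {
  stopifnot(inherits(entry, "fit_entry"))
  if (entry$direction != "return") return(entry)
  p <- entry$problem
  p$x_s <- c(p$x_s[7:12], p$x_s[1:6])
  p$x_f <- c(p$x_f[4:6], p$x_f[1:3])
  a1 <- entry$avg2; a1$entity <- "subject1"
  a2 <- entry$avg1; a2$entity <- "subject2"
  out <- entry
  out$problem <- p
  out$avg1 <- a1
  out$avg2 <- a2
  out
}

#' IOC objective: misfit of the OC model at given weights
#'
#' For every entry the coupled OC problem is solved with the candidate
#' weights and the generated trajectories are scored against the entry's
#' averages with the curve distances. The per-entry score is
#' `d_xy1 + d_xy2 + (d_theta1 + d_theta2) / 2` (the half weight puts the
#' linear and angular terms on the same magnitude) and the objective is the
#' mean score over entries. Entries whose inner solve fails contribute a
#' fixed `penalty` so the outer search always sees a total function.
#'
#' @param weights a [cost_weights()].
#' @param dataset a [fit_dataset()].
#' @param solver_options list passed to [solve_oc()] (e.g. `max_iter`, `tol`).
#' @param cache optional environment holding per-entry control warm starts;
#'   speeds up repeated evaluations during fitting.
#' @param penalty score assigned to failed entries (default 10).
#' @param role_switch apply [role_switch_return()] to return entries before
#'   solving (default `TRUE`, the fitting convention).
#' @return list with `objective`, `per_entry` data frame and `n_failed`.
#' @export
ioc_objective <- function(weights, dataset, solver_options = list(),
                          cache = NULL, penalty = 10, role_switch = TRUE) {
  stopifnot(inherits(weights, "cost_weights"), inherits(dataset, "fit_dataset"))
  scores <- numeric(dataset$n_traj)
  rows <- vector("list", dataset$n_traj)
  n_failed <- 0L
  for (j in seq_len(dataset$n_traj)) {
    e <- dataset$entries[[j]]
    if (role_switch) e <- role_switch_return(e)
    init <- if (!is.null(cache)) cache[[paste0("e", j)]] else NULL
    args <- c(list(problem = e$problem, weights = weights,
                   n_out = e$avg1$n, init = init), solver_options)
    sol <- tryCatch(do.call(solve_oc, args), error = function(err) NULL)
    if (is.null(sol)) {
      n_failed <- n_failed + 1L
      scores[j] <- penalty
      rows[[j]] <- data.frame(entry = j, goal_id = e$goal_id,
                              direction = e$direction, config = e$config,
                              d_xy1 = NA, d_xy2 = NA,
                              d_theta1 = NA, d_theta2 = NA,
                              score = penalty, failed = TRUE)
      next
    }
    if (!is.null(cache)) cache[[paste0("e", j)]] <- sol$U
    d1 <- curve_distance(e$avg1, sol$subject1)
    d2 <- curve_distance(e$avg2, sol$subject2)
    scores[j] <- d1$d_xy + d2$d_xy + 0.5 * (d1$d_theta + d2$d_theta)
    rows[[j]] <- data.frame(entry = j, goal_id = e$goal_id,
                            direction = e$direction, config = e$config,
                            d_xy1 = d1$d_xy, d_xy2 = d2$d_xy,
                            d_theta1 = d1$d_theta, d_theta2 = d2$d_theta,
                            score = scores[j], failed = FALSE)
  }
  list(objective = mean(scores), per_entry = do.call(rbind, rows),
       n_failed = n_failed)
}

# one-dimensional minimization along direction `dir` in log-weight space:
# 3-point parabolic step with safeguarding, few objective evaluations.
line_min <- function(fun, z, dir, f0, step = 0.35, max_evals = 6L) {
  evals <- 0L
  f <- function(lam) { evals <<- evals + 1L; fun(z + lam * dir) }
  lams <- c(0, -step, step)
  fs <- c(f0, f(-step), f(step))
  best <- which.min(fs)
  # expand in the descending direction while it keeps improving
  while (best != 1L && evals < max_evals) {
    lam_new <- 2 * lams[best]
    f_new <- f(lam_new)
    if (f_new < fs[best]) { lams <- c(lams, lam_new); fs <- c(fs, f_new); best <- length(fs) }
    else { lams <- c(lams, lam_new); fs <- c(fs, f_new); break }
  }
  # parabolic refinement through the three best points
  if (evals < max_evals && length(lams) >= 3L) {
    o <- order(fs)[1:3]
    x1 <- lams[o[1L]]; x2 <- lams[o[2L]]; x3 <- lams[o[3L]]
    y1 <- fs[o[1L]]; y2 <- fs[o[2L]]; y3 <- fs[o[3L]]
    den <- (x1 - x2) * (x1 - x3) * (x2 - x3)
    if (abs(den) > 1e-12) {
      a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / den
      b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / den
      if (a > 1e-12) {
        lam_p <- max(min(-b / (2 * a), max(lams) + step), min(lams) - step)
        f_p <- f(lam_p)
        lams <- c(lams, lam_p); fs <- c(fs, f_p)
      }
    }
  }
  best <- which.min(fs)
  list(lam = lams[best], f = fs[best], evals = evals)
}

#' Fit cost weights by bi-level inverse optimal control
#'
#' Minimizes [ioc_objective()] over the weights with a derivative-free
#' Powell-type conjugate-direction search. Nonnegativity is enforced by
#' searching in log-weight space; after each sweep over the direction set the
#' direction of largest decrease is replaced by the overall displacement
#' (Powell's update). Restarts perturb the best-so-far point with a fixed
#' seed. The returned trace is the best objective after each evaluation and
#' is non-increasing by construction.
#'
#' @param dataset a [fit_dataset()].
#' @param init initial [cost_weights()].
#' @param budget total objective-evaluation budget (default 600).
#' @param restarts number of restart perturbations (default 3; the budget is
#'   shared across restarts).
#' @param step initial log-space line-search step (0.35 is roughly a factor
#'   1.4 on a weight).
#' @param tol stop a sweep cycle when the relative objective decrease falls
#'   below this value.
#' @param improve_tol minimal absolute objective decrease for a line-search
#'   move to be accepted (default 1e-4 m-equivalents). Guards the search
#'   against drifting along flat directions of the objective -- the overall
#'   weight scale, and the constant time-pressure weight when horizons are
#'   fixed -- where numerically tiny fluctuations would otherwise look like
#'   descent.
#' @param solver_options list passed to [solve_oc()] for the inner solves.
#' @param seed seed for the restart perturbations.
#' @return a list of class `fit_result`: `weights`, `objective`, `trace`,
#'   `per_entry`, `evaluations`, `budget_exhausted`.
#' @export
fit_weights <- function(dataset, init, budget = 600L, restarts = 3L,
                        step = 0.35, tol = 1e-4, improve_tol = 1e-4,
                        solver_options = list(max_iter = 80L, tol = 1e-6),
                        seed = 20L) {
  stopifnot(inherits(dataset, "fit_dataset"), inherits(init, "cost_weights"))
  ds <- dataset   # ioc_objective applies the role switch itself
  cache <- new.env(parent = emptyenv())
  npar <- 15L
  evals <- 0L
  trace <- numeric(0)
  best_f <- Inf
  best_z <- NULL
  eval_fun <- function(z) {
    evals <<- evals + 1L
    w <- cost_weights(exp(z[1:11]), exp(z[12:15]))
    f <- ioc_objective(w, ds, solver_options = solver_options,
                       cache = cache)$objective
    # margin guards best-point tracking against flat-direction jitter
    if (f < best_f - improve_tol / 10 || is.null(best_z)) { best_f <<- f; best_z <<- z }
    trace <<- c(trace, best_f)
    f
  }
  z0 <- log(pmax(c(init$alpha, init$beta), 1e-12))
  f0 <- eval_fun(z0)
  rng <- local({ set.seed(seed); function(n) stats::rnorm(n) })
  for (r in seq_len(max(1L, restarts))) {
    z <- if (r == 1L) z0 else best_z + 0.15 * rng(npar)
    f <- if (r == 1L) f0 else eval_fun(z)
    dirs <- diag(npar)
    repeat {
      if (evals >= budget) break
      f_start <- f
      z_start <- z
      biggest_drop <- 0
      drop_idx <- 1L
      for (d in seq_len(npar)) {
        if (evals >= budget) break
        lm <- line_min(eval_fun, z, dirs[, d], f, step = step,
                       max_evals = min(6L, budget - evals))
        if (lm$f < f - improve_tol) {
          if (f - lm$f > biggest_drop) { biggest_drop <- f - lm$f; drop_idx <- d }
          z <- z + lm$lam * dirs[, d]
          f <- lm$f
        }
      }
      disp <- z - z_start
      if (sqrt(sum(disp^2)) > 1e-10) {
        dirs[, drop_idx] <- disp / sqrt(sum(disp^2))
        if (evals < budget) {
          lm <- line_min(eval_fun, z, dirs[, drop_idx], f, step = step,
                         max_evals = min(6L, budget - evals))
          if (lm$f < f - improve_tol) { z <- z + lm$lam * dirs[, drop_idx]; f <- lm$f }
        }
      }
      if (f_start - f < tol * max(1, abs(f_start)) || evals >= budget) break
    }
    if (evals >= budget) break
  }
  w_best <- cost_weights(exp(best_z[1:11]), exp(best_z[12:15]))
  final <- ioc_objective(w_best, ds, solver_options = solver_options,
                         cache = cache)
  structure(list(weights = w_best, objective = final$objective,
                 trace = trace, per_entry = final$per_entry,
                 evaluations = evals, budget_exhausted = evals >= budget),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective %.5f after %d evaluations%s\n",
              x$objective, x$evaluations,
              if (x$budget_exhausted) " (budget exhausted)" else ""))
  print(x$weights)
  invisible(x)
}
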