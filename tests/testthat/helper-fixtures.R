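# Fixtures built in code: marker series, simple trajectories, manual trial
# records. No data files are read.

wrap_pi <- function(a) atan2(sin(a), cos(a))

# uniform-rate marker series from a list of n x 3 matrices
make_series <- function(coords, labels, rate = 200) {
  n <- nrow(coords[[1L]])
  xyz <- array(NA_real_, dim = c(n, 3L, length(coords)))
  for (m in seq_along(coords)) xyz[, , m] <- coords[[m]]
  marker_series(seq(0, by = 1 / rate, length.out = n), xyz, labels, rate)
}

# four pelvis markers at the corners of a unit square centred at the origin,
# ASIS side facing +x, held constant for n samples, then rigidly moved
square_pelvis <- function(n = 10, angle = 0, shift = c(0, 0)) {
  base <- list(LASI = c(0.5, 0.5, 1), RASI = c(0.5, -0.5, 1),
               LPSI = c(-0.5, 0.5, 1), RPSI = c(-0.5, -0.5, 1))
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  coords <- lapply(base, function(p) {
    q <- c(R %*% p[1:2] + shift, p[3L])
    matrix(rep(q, each = n), n, 3L)
  })
  make_series(coords, names(base))
}

# three corners of a length x width rectangle centred at `centre`, rotated by
# `angle`, ordered around the rectangle
table_corners <- function(n = 10, angle = 0, centre = c(0, 0),
                          length = 1.22, width = 0.8) {
  hl <- length / 2; hw <- width / 2
  pts <- list(c(-hl, -hw), c(hl, -hw), c(hl, hw))   # P1-P2 long edge, P2-P3 short
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  coords <- lapply(pts, function(p) {
    q <- c(R %*% p + centre, 0.77)
    matrix(rep(q, each = n), n, 3L)
  })
  make_series(coords, c("C1", "C2", "C3"))
}

# smooth random trajectory for metric property tests
random_traj <- function(n = 50, entity = "subject1") {
  tau <- seq(0, 1, length.out = n)
  sm <- function() {
    a <- stats::rnorm(4) / (1:4)
    as.vector(sin(pi * outer(tau, 1:4)) %*% a) + stats::rnorm(1) + tau * stats::rnorm(1)
  }
  trajectory(sm(), sm(), 0.5 * sm(), entity = entity)
}

# apply a planar rigid motion (rotation `ang` then translation) to a trajectory
rigid_move <- function(tr, ang, tx, ty) {
  trajectory(cos(ang) * tr$x - sin(ang) * tr$y + tx,
             sin(ang) * tr$x + cos(ang) * tr$y + ty,
             tr$theta + ang, t = tr$t, entity = tr$entity,
             normalized = tr$normalized)
}

# manual trial record for analysis tests
make_trial <- function(pair_id, goal_id, scenario, direction, config,
                       travel_time, s1, s2, tab, rep = 1L) {
  s1$entity <- "subject1"; s2$entity <- "subject2"; tab$entity <- "table"
  attr(s1, "config") <- config; attr(s2, "config") <- config
  attr(tab, "config") <- config
  structure(list(pair_id = pair_id, goal_id = goal_id, scenario = scenario,
                 direction = direction, config = config, rep = rep,
                 travel_time = travel_time,
                 subject1 = s1, subject2 = s2, table = tab),
            class = "trial_record")
}

as_dataset <- function(trials) structure(trials, class = "trial_dataset")

# straight-line constant-heading trajectory
line_traj <- function(from, to, theta = 0, n = 50, entity = "subject1") {
  trajectory(seq(from[1L], to[1L], length.out = n),
             seq(from[2L], to[2L], length.out = n),
             rep(theta, n), entity = entity)
}
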