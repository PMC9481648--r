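# copair

Kinematics and coupled optimal-control modelling of two humans carrying a
table together.

When a pair carries a table, the object couples their locomotion: the
carriers stay roughly a table-length apart, roughly facing each other, one
walking forward and one backward, and together they choose a path and a
final table orientation. `copair` implements the complete analysis pipeline
for such experiments, exercised end-to-end on a synthetic emulation of the
canonical study design (20 pairs, 9 goal positions 2.7–5.4 m away, 3
knowledge scenarios, forward and return paths — 1080 trials, 3240
centre-of-mass trajectories):

* **Preprocessing** — zero-phase 4th-order Butterworth filtering (10 Hz) of
  200 Hz marker data, trial segmentation by table lift height (5 mm above
  the floor), pelvis and table planar-pose extraction, heading unwrapping
  and time normalization to 500 samples.
* **Trajectory metrics** — the pointwise linear and angular curve distances

  $$d_{xy} = \frac{1}{N}\sum_i \lVert p_{1,i}-p_{2,i}\rVert, \qquad
    d_\theta = \frac{1}{N}\sum_i \lvert\theta_{1,i}-\theta_{2,i}\rvert,$$

  trajectory averaging, forward/return symmetry, and
  configuration-optimality classification from per-subject travelled
  distances.
* **Coupled OC model** — two planar holonomic agents (forward, lateral and
  angular accelerations as controls) coupled by exponential barriers on
  their separation (1.6–2.1 m) and mutual facing (π/3), with a running cost
  (time pressure, control effort, bearing-to-goal errors, barriers) and a
  terminal cost (goal pose and terminal velocities), solved by a DDP/iLQR
  trajectory optimizer.
* **Inverse optimal control** — bi-level fitting of the 11 running + 4
  terminal cost weights to average trajectories with a Powell-type
  derivative-free search in log-weight space, including the return-path
  role-switch convention.
* **Strategy analysis** — travel-time, path-proximity, optimality-rate,
  symmetry and variability reports with the non-parametric battery
  (Kruskal–Wallis, Mann–Whitney, Fisher exact, Shapiro–Wilk gate).

## Worked example

Solve the coupled model for an oblique goal that requires a quarter-turn of
the table, then generate a small synthetic cohort and summarise it:

```r
library(copair)
w <- reference_weights()

goal <- make_goal_layout()[[6]]          # 3.68 m away, quarter-turn
p <- goal_problem(goal, config = "A", direction = "forward")
sol <- solve_oc(p, w)
sol
#> <oc_solution> T = 5.05 s, cost 31.4431 (warm 131.7864), 13 iterations
#>   terminal miss: 0.043 / 0.055 m, 0.039 / 0.033 rad; chi = 0 on 70.6% of samples
```

The pair reaches the goal with a 4–6 cm miss (the terminal constraint is a
soft cost, so generated trajectories may not hit the goal exactly); during
the pivot the separation barrier activates on part of the path — the
barrier weights are deliberately weak couplings.

```r
des <- study_design(n_pairs = 5L, seed = 42L)
ds <- generate_dataset(des, w)           # OC-model base + smooth path noise
vr <- variability_report(ds, des$goals)
vr$overall
#>     entity mean_d_xy    sd_d_xy mean_d_theta sd_d_theta
#> 1 subject1 0.1642985 0.03707333    0.1588957 0.05183507
#> 2 subject2 0.1595724 0.04027099    0.1555306 0.05273307
#> 3    table 0.1210686 0.02884788    0.1156157 0.03837157

tt <- travel_time_comparison(ds)
tt$summary
#>                cell  n   mean_s     sd_s
#> 1         scenario1 45 9.906459 2.516003
#> 2         scenario2 45 8.688940 1.967205
#> 3 scenario3.forward 45 8.497869 1.549019
#> 4  scenario3.return 45 8.228518 1.372190
tt$omnibus_p
#> [1] 0.002742...
```

Trial-to-average distances sit near the design's 0.20 m / 0.20 rad noise
level, the table varies less than the carriers, and the travel-time rank
test already detects the leadership effect (shared knowledge speeds the
task up) at 5 pairs.

Weights can be re-identified from trajectories by inverse optimal control:

```r
entries <- ioc_default_layout()          # 31 entries: 13 forward, 18 return
fds <- make_fit_dataset(w, layout = entries[1:6, ], dt = 0.1)
fit <- fit_weights(fds, init = w, budget = 60)
```

See the vignette (`vignettes/pair-carriage-model.Rmd`) for the model, its
assumptions, the numerical choices and the generator's design.

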