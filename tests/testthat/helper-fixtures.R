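## Normalised pendulum: m g L = 1 N m, W r = 0.01 N m, omega = 10 rad/s.
## Makes the Coulomb decrement exactly 2 mu W r / (m g L) = mu / 50 readable.
norm_config <- function(sample_rate = 60, start_angle = 12) {
  pendulum_config(arm_mass = 1, com_distance = 0.1, gravity = 10,
                  moment_of_inertia = 0.01, joint_load = 10,
                  joint_radius = 0.001, start_angle = start_angle,
                  sample_rate = sample_rate)
}

## Arm markers evenly spaced on a circle about the pivot (centroid at the
## pivot) and base markers on a wider circle: the configuration for which
## the first-order angle-noise prediction sd/(r sqrt(n)) is clean.
circle_layout <- function(r_arm = 20, r_base = 60) {
  ang_a <- deg2rad_(c(45, 135, 225, 315))
  ang_b <- deg2rad_(c(0, 90, 180, 270))
  marker_layout(arm = r_arm * cbind(cos(ang_a), sin(ang_a)),
                base = r_base * cbind(cos(ang_b), sin(ang_b)),
                pivot = c(0, 0))
}

deg2rad_ <- function(x) x * pi / 180

## Bare angle container accepted by render_markers / detect_peaks.
fake_traj <- function(times, angles) list(times = times, angles = angles)

## R^2 of a simple straight-line fit.
line_r2 <- function(x, y) summary(stats::lm(y ~ x))$r.squared

## Profiles with all randomness switched off (degenerate generator).
noiseless_profiles <- function() {
  lapply(default_profiles(), function(p) {
    p$animal_cv <- 0
    p$trial_sd <- 0
    p
  })
}

## Plateau-level score table for one joint at the given category levels.
plateau_df <- function(structure, surface, safranin) {
  data.frame(
    category = rep(c("structure", "surface", "safranin"),
                   times = c(length(structure), length(surface),
                             length(safranin))),
    score = c(structure, surface, safranin))
}
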