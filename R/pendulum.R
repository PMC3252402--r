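#' Passive pendulum configuration
#'
#' Geometry, inertia and sampling parameters of the passive pendulum used to
#' measure whole-joint friction. The knee joint is the fulcrum; the pendulum
#' arm (default 50 g, about twice a mouse's body weight) hangs from it and is
#' released from a small start angle. Angles are expressed as deviation from
#' the vertical equilibrium; the anatomical resting flexion of the knee
#' (about 70 degrees in ambulating rodents) is carried as metadata only and
#' never enters the dynamics.
#'
#' Defaults are mouse-scale: a 12 mm pivot-to-centre-of-mass distance, a
#' slender-arm moment of inertia `(4/3) m L^2`, joint load equal to the arm
#' weight, and a 1 mm effective frictional moment arm at the fulcrum. The
#' measurement chain is a round trip (the same configuration converts decay
#' slope back to friction coefficient), so results are insensitive to the
#' specific geometry values as long as simulator and estimator share them.
#'
#' @param arm_mass Arm mass in kg.
#' @param com_distance Pivot to arm centre-of-mass distance in m.
#' @param gravity Gravitational acceleration in m/s^2.
#' @param moment_of_inertia Moment of inertia about the pivot in kg m^2.
#' @param joint_load Normal force across the joint surfaces in N.
#' @param joint_radius Effective frictional moment arm at the fulcrum in m.
#' @param equilibrium_flexion Anatomical knee flexion at equilibrium in
#'   degrees (metadata).
#' @param start_angle Release angle in degrees (deviation from equilibrium);
#'   must not exceed 30 degrees in magnitude.
#' @param sample_rate Motion-capture sampling rate in Hz.
#' @return An object of class `pendulum_config`.
#' @export
pendulum_config <- function(arm_mass = 0.050,
                            com_distance = 0.012,
                            gravity = 9.81,
                            moment_of_inertia = (4 / 3) * arm_mass * com_distance^2,
                            joint_load = arm_mass * gravity,
                            joint_radius = 0.001,
                            equilibrium_flexion = 70,
                            start_angle = 12,
                            sample_rate = 60) {
  check_positive(arm_mass, "arm_mass")
  check_positive(com_distance, "com_distance")
  check_positive(gravity, "gravity")
  check_positive(moment_of_inertia, "moment_of_inertia")
  check_positive(joint_load, "joint_load")
  check_positive(joint_radius, "joint_radius")
  check_positive(sample_rate, "sample_rate")
  if (!is.finite(start_angle) || abs(start_angle) > 30)
    jf_error("start_angle must satisfy |start_angle| <= 30 degrees",
             "config_error")
  cfg <- structure(
    list(arm_mass = arm_mass, com_distance = com_distance, gravity = gravity,
         moment_of_inertia = moment_of_inertia, joint_load = joint_load,
         joint_radius = joint_radius, equilibrium_flexion = equilibrium_flexion,
         start_angle = start_angle, sample_rate = sample_rate),
    class = "pendulum_config")
  # natural frequency must be finite and positive
  stopifnot(is.finite(natural_frequency(cfg)), natural_frequency(cfg) > 0)
  cfg
}

#' @export
print.pendulum_config <- function(x, ...) {
  cat("Passive pendulum configuration\n")
  cat(sprintf("  arm mass          %.4g kg\n", x$arm_mass))
  cat(sprintf("  com distance      %.4g m\n", x$com_distance))
  cat(sprintf("  moment of inertia %.4g kg m^2\n", x$moment_of_inertia))
  cat(sprintf("  joint load        %.4g N\n", x$joint_load))
  cat(sprintf("  joint radius      %.4g m\n", x$joint_radius))
  cat(sprintf("  start angle       %.4g deg, sampled at %.4g Hz\n",
              x$start_angle, x$sample_rate))
  cat(sprintf("  natural frequency %.4g rad/s (%.3g Hz)\n",
              natural_frequency(x), natural_frequency(x) / (2 * pi)))
  invisible(x)
}

## Restoring torque coefficient m g L (N m) and frictional torque capacity
## mu W r are the two scales of the decay model.
restoring_coeff <- function(config) {
  config$arm_mass * config$gravity * config$com_distance
}

friction_torque_arm <- function(config) {
  config$joint_load * config$joint_radius
}

#' Small-angle natural frequency of the pendulum, `sqrt(m g L / I)` in rad/s.
#' @param config A [pendulum_config()].
#' @return Angular frequency in rad/s.
#' @export
natural_frequency <- function(config) {
  sqrt(restoring_coeff(config) / config$moment_of_inertia)
}

#' Friction parameters of the joint fulcrum
#'
#' Coulomb (dry) friction produces a constant opposing torque `mu W r` and a
#' linear amplitude decay; an optional viscous term `c` (velocity-
#' proportional torque) is provided as a model extension and produces
#' exponential decay. The measurement model of the study corresponds to
#' `viscous_coeff = 0`.
#'
#' @param mu Dimensionless Coulomb coefficient of friction (>= 0).
#' @param viscous_coeff Viscous damping coefficient in N m s/rad (>= 0).
#' @return An object of class `friction_params`.
#' @export
friction_params <- function(mu = 0, viscous_coeff = 0) {
  check_nonnegative(mu, "mu")
  check_nonnegative(viscous_coeff, "viscous_coeff")
  structure(list(mu = mu, viscous_coeff = viscous_coeff),
            class = "friction_params")
}

## Duration long enough for the envelope to decay from the start angle to
## below min_amplitude under Coulomb friction, with margin. Capped for very
## low friction where decay is slow.
auto_duration <- function(config, friction, min_amplitude = deg2rad(1),
                          max_duration = 60) {
  omega <- natural_frequency(config)
  half_period <- pi / omega
  mu <- friction$mu
  theta0 <- abs(deg2rad(config$start_angle))
  if (mu <= 0 && friction$viscous_coeff <= 0) return(min(20 * half_period, max_duration))
  if (mu > 0) {
    dec <- 2 * mu * friction_torque_arm(config) / restoring_coeff(config)
    n_half <- (theta0 - 0.5 * min_amplitude) / dec + 6
    return(min(max_duration, max(1.1 * n_half * half_period, 4 * half_period)))
  }
  # viscous only: time for amplitude to fall by a factor 1e3
  tau <- 2 * config$moment_of_inertia / friction$viscous_coeff
  min(max_duration, max(log(1000) * tau, 4 * half_period))
}

#' Simulate the free oscillation of the passive pendulum
#'
#' Integrates the compound-pendulum equation of motion with Coulomb and
#' (optionally) viscous damping at the fulcrum,
#' `I d2theta/dt2 = -m g L sin(theta) - sign(dtheta/dt) mu W r - c dtheta/dt`,
#' from rest at the start angle. Integration proceeds piecewise between
#' velocity zero crossings (located by root finding) so that the sign
#' discontinuity of Coulomb friction is handled exactly; at each turning
#' point the stick condition `|m g L sin(theta)| <= mu W r` is re-evaluated
#' and, once it holds, the pendulum is held at that angle for the remainder
#' of the trial.
#'
#' @param config A [pendulum_config()].
#' @param friction A [friction_params()].
#' @param duration Trial length in seconds; `NULL` chooses a length long
#'   enough for the envelope to decay below one degree (capped at 60 s).
#' @return A `trial_trajectory` with components `times` (s, uniform grid at
#'   the configured sample rate), `angles` (rad, deviation from equilibrium),
#'   `angular_velocities` (rad/s), `stopped_at` (s, `NA` if motion persists
#'   to the end), `extrema` (data frame of exact turning points from the
#'   event-detecting integrator), and the generating `config`/`friction`.
#' @export
simulate_free_oscillation <- function(config, friction = friction_params(),
                                      duration = NULL) {
  stopifnot(inherits(config, "pendulum_config"),
            inherits(friction, "friction_params"))
  if (is.null(duration)) duration <- auto_duration(config, friction)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    jf_error("duration must be a single positive number", "config_error")

  mgl <- restoring_coeff(config)
  wr <- friction_torque_arm(config)
  inertia <- config$moment_of_inertia
  mu <- friction$mu
  cvis <- friction$viscous_coeff
  rate <- config$sample_rate
  omega <- natural_frequency(config)
  short <- duration < pi / omega

  n <- floor(duration * rate + 1e-9)
  times <- (0:n) / rate
  theta <- rep(NA_real_, n + 1L)
  vel <- rep(NA_real_, n + 1L)

  th <- deg2rad(config$start_angle)
  theta[1L] <- th
  vel[1L] <- 0
  gi <- 2L                       # next grid slot to fill
  tcur <- 0
  stopped_at <- NA_real_
  ext_t <- numeric(0)
  ext_a <- numeric(0)
  kick <- 1e-6                   # analytic Taylor step off each rest point

  segment <- 0L
  repeat {
    segment <- segment + 1L
    # stick check at a rest point
    if (abs(mgl * sin(th)) <= mu * wr * (1 + 1e-12)) {
      stopped_at <- tcur
      break
    }
    s <- -sign(sin(th))          # sign of the impending velocity
    acc0 <- (-mgl * sin(th) - s * mu * wr) / inertia
    t1 <- tcur + kick
    th1 <- th + 0.5 * acc0 * kick^2
    v1 <- acc0 * kick
    while (gi <= n + 1L && times[gi] <= t1 + 1e-15) {
      dt <- times[gi] - tcur
      theta[gi] <- th + 0.5 * acc0 * dt^2
      vel[gi] <- acc0 * dt
      gi <- gi + 1L
    }
    if (t1 >= duration) break

    remaining <- if (gi <= n + 1L) times[gi:(n + 1L)] else numeric(0)
    remaining <- remaining[remaining > t1 + 1e-15]
    ts <- c(t1, remaining)
    if (length(ts) == 1L || ts[length(ts)] < duration - 1e-12)
      ts <- c(ts, duration)

    deriv <- function(t, y, parms) {
      list(c(y[2L], (-mgl * sin(y[1L]) - s * mu * wr - cvis * y[2L]) / inertia))
    }
    rootf <- function(t, y, parms) y[2L]
    sol <- deSolve::lsodar(y = c(th1, v1), times = ts, func = deriv,
                           parms = NULL, rootfunc = rootf,
                           rtol = 1e-10, atol = 1e-12)
    if (any(!is.finite(sol[, 2L])) || any(!is.finite(sol[, 3L])))
      jf_error(sprintf(
        "integration failure: non-finite state in segment %d near t = %.4f s",
        segment, tcur), "integration_error")

    sol_t <- sol[, 1L]
    troot <- attr(sol, "troot")
    rooted <- length(troot) > 0L
    for (k in seq_along(sol_t)[-1L]) {
      if (gi <= n + 1L && abs(sol_t[k] - times[gi]) < 1e-9) {
        theta[gi] <- sol[k, 2L]
        vel[gi] <- sol[k, 3L]
        gi <- gi + 1L
      }
    }
    if (!rooted) break           # reached duration while still moving
    tcur <- troot[1L]
    th <- sol[nrow(sol), 2L]
    ext_t <- c(ext_t, tcur)
    ext_a <- c(ext_a, th)
    if (tcur >= duration) break
  }

  if (gi <= n + 1L) {            # hold at rest (or final) angle
    theta[gi:(n + 1L)] <- th
    vel[gi:(n + 1L)] <- 0
    gi <- n + 2L
  }

  if (short)
    warning("duration is shorter than one half period of the pendulum")

  structure(
    list(times = times, angles = theta, angular_velocities = vel,
         stopped_at = stopped_at,
         extrema = data.frame(time = ext_t, angle = ext_a),
         short_duration = short, config = config, friction = friction),
    class = "trial_trajectory")
}

#' @export
print.trial_trajectory <- function(x, ...) {
  cat(sprintf("Pendulum trial: %d samples at %g Hz (%.3g s)\n",
              length(x$times), x$config$sample_rate, max(x$times)))
  cat(sprintf("  start angle %.3g deg, mu = %.4g, c = %.4g N m s/rad\n",
              x$config$start_angle, x$friction$mu, x$friction$viscous_coeff))
  if (is.na(x$stopped_at)) cat("  motion persists to end of trial\n")
  else cat(sprintf("  stuck at t = %.3f s (angle %.4g deg)\n",
                   x$stopped_at, rad2deg(x$angles[length(x$angles)])))
  cat(sprintf("  %d turning points detected by the integrator\n",
              nrow(x$extrema)))
  invisible(x)
}

#' Total mechanical energy of a trajectory at each sample
#'
#' `E = I omega^2 / 2 + m g L (1 - cos theta)`, in joules. With non-negative
#' Coulomb and viscous coefficients this is non-increasing (up to integrator
#' tolerance), which the test suite verifies.
#'
#' @param traj A `trial_trajectory`.
#' @return Numeric vector of energies (J).
#' @export
trajectory_energy <- function(traj) {
  cfg <- traj$config
  0.5 * cfg$moment_of_inertia * traj$angular_velocities^2 +
    restoring_coeff(cfg) * (1 - cos(traj$angles))
}
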