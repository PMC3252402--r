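#' Detect oscillation extrema of an angle series
#'
#' Local extrema are located by sign changes of the discrete derivative and
#' refined by a quadratic fit through the three samples straddling each
#' extremum (at 60 Hz sampling of a 1-2 Hz swing, raw samples alias peak
#' heights by up to about a percent). Runs of exactly equal adjacent samples
#' take the earlier sample as the vertex centre. The sequence is truncated
#' at the first extremum whose amplitude falls below `min_amplitude`
#' (Coulomb decay is linear only while motion persists; the tail near stick
#' is excluded), and alternating-sign ordering is enforced.
#'
#' @param series An `angle_series` (or a list with `times` and `angles` in
#'   radians) uniformly sampled.
#' @param min_amplitude Smallest retained amplitude in rad (default 1
#'   degree).
#' @return A `peak_sequence` data frame with columns `index` (half-cycle
#'   counter from 0), `time` (s, sub-sample refined), `amplitude` (rad,
#'   absolute deviation from equilibrium) and `sign`.
#' @export
detect_peaks <- function(series, min_amplitude = deg2rad(1)) {
  check_positive(min_amplitude, "min_amplitude")
  a <- series$angles
  tt <- series$times
  n <- length(a)
  if (n >= 3L && stats::sd(diff(tt)) > 1e-6 * mean(diff(tt)))
    jf_error("series must be uniformly sampled", "config_error")
  d <- diff(a)
  s <- sign(d)
  nz <- which(s != 0)
  centers <- integer(0)
  if (length(nz) >= 2L) {
    s_nz <- s[nz]
    ch <- which(s_nz[-length(s_nz)] * s_nz[-1L] < 0)
    centers <- nz[ch] + 1L
  }
  if (length(centers) == 0L)
    jf_error("insufficient oscillation: no extrema found", "insufficient_oscillation_error")

  h <- tt[2L] - tt[1L]
  y1 <- a[centers - 1L]; y2 <- a[centers]; y3 <- a[centers + 1L]
  q <- (y3 - y1) / 2
  h2 <- (y1 - 2 * y2 + y3) / 2
  delta <- ifelse(abs(h2) > 1e-300, -q / (2 * h2), 0)
  delta <- pmax(pmin(delta, 1), -1)
  val <- y2 + q * delta + h2 * delta^2
  ptime <- tt[centers] + delta * h
  amp <- abs(val)
  sgn <- sign(val)

  # truncate at the first sub-threshold extremum
  small <- which(amp < min_amplitude)
  keep_n <- if (length(small)) small[1L] - 1L else length(amp)
  if (keep_n < 4L)
    jf_error(sprintf(
      "insufficient oscillation: only %d extrema above min_amplitude (need 4)",
      keep_n), "insufficient_oscillation_error")
  idx <- seq_len(keep_n)
  ptime <- ptime[idx]; amp <- amp[idx]; sgn <- sgn[idx]

  # enforce alternating signs: of same-signed neighbours keep the larger
  keep <- rep(TRUE, length(amp))
  last <- 1L
  for (k in seq_along(amp)[-1L]) {
    if (sgn[k] == sgn[last]) {
      if (amp[k] > amp[last]) { keep[last] <- FALSE; last <- k }
      else keep[k] <- FALSE
    } else last <- k
  }
  ptime <- ptime[keep]; amp <- amp[keep]; sgn <- sgn[keep]
  if (length(amp) < 4L)
    jf_error("insufficient oscillation: fewer than 4 alternating extrema",
             "insufficient_oscillation_error")

  structure(data.frame(index = seq_along(amp) - 1L, time = ptime,
                       amplitude = amp, sign = sgn),
            class = c("peak_sequence", "data.frame"))
}

#' Stanton linear amplitude-decay fit
#'
#' Ordinary least squares of extremum amplitude against half-cycle index.
#' Under Coulomb friction the envelope decays by a constant amount per half
#' cycle, so the (sign-normalised, positive for decay) slope is the
#' per-half-cycle amplitude decrement.
#'
#' @param peaks A `peak_sequence` from [detect_peaks()] (>= 4 peaks).
#' @return A `stanton_fit` list: `slope` (rad per half-cycle, positive for a
#'   decaying envelope), `intercept` (rad), `r_squared`, `n_peaks`, and
#'   `flag` (`"no-decay"` when the amplitudes have zero variance, in which
#'   case `slope = 0` and `r_squared = 1` by convention).
#' @export
fit_stanton <- function(peaks) {
  amp <- peaks$amplitude
  idx <- peaks$index
  if (length(amp) < 4L)
    jf_error("need at least 4 peaks for the decay fit",
             "insufficient_oscillation_error")
  if (stats::var(amp) == 0) {
    return(structure(list(slope = 0, intercept = amp[1L], r_squared = 1,
                          n_peaks = length(amp), flag = "no-decay"),
                     class = "stanton_fit"))
  }
  fit <- stats::lm(amp ~ idx)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits warn
  structure(list(slope = -unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2, n_peaks = length(amp),
                 flag = NA_character_),
            class = "stanton_fit")
}

#' Convert a decay slope to a coefficient of friction
#'
#' By energy balance at small angles, Coulomb friction removes
#' `2 mu W r (theta1 + theta2) / 2`... precisely, successive extrema obey
#' `theta1 - theta2 = 2 mu W r / (m g L)`, so
#' `mu = slope (m g L) / (2 W r)` with `slope` the per-half-cycle amplitude
#' decrement from [fit_stanton()].
#'
#' @param slope Per-half-cycle amplitude decrement in rad (>= 0 after decay
#'   sign normalisation).
#' @param config The [pendulum_config()] used for the trial.
#' @param tol Negative slopes smaller in magnitude than `tol` are clamped to
#'   zero; a growing envelope beyond that is an error.
#' @return `mu_hat`, the dimensionless coefficient of friction.
#' @export
estimate_cof <- function(slope, config, tol = 1e-9) {
  stopifnot(inherits(config, "pendulum_config"))
  if (!is.finite(slope))
    jf_error("slope must be finite", "invalid_decay_error")
  if (slope < -tol)
    jf_error("invalid decay: envelope grows (negative decrement)",
             "invalid_decay_error")
  max(slope, 0) * restoring_coeff(config) / (2 * friction_torque_arm(config))
}

#' Estimate the coefficient of friction for one trial
#'
#' Convenience chain [detect_peaks()] -> [fit_stanton()] -> [estimate_cof()]
#' applied to a tracked angle series.
#'
#' @param series An `angle_series`.
#' @param config The [pendulum_config()] of the trial.
#' @param min_amplitude Passed to [detect_peaks()].
#' @return A `cof_estimate` list: `slope`, `intercept`, `r_squared`,
#'   `mu_hat`, `n_peaks`, `flag`.
#' @export
estimate_trial <- function(series, config, min_amplitude = deg2rad(1)) {
  peaks <- detect_peaks(series, min_amplitude = min_amplitude)
  fit <- fit_stanton(peaks)
  mu <- estimate_cof(fit$slope, config)
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, mu_hat = mu,
                 n_peaks = fit$n_peaks, flag = fit$flag),
            class = "cof_estimate")
}

#' @export
print.cof_estimate <- function(x, ...) {
  cat(sprintf(
    "CoF estimate: mu = %.4g (slope %.4g rad/half-cycle, R^2 = %.5f, %d peaks)\n",
    x$mu_hat, x$slope, x$r_squared, x$n_peaks))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Average replicate trial estimates for one joint
#'
#' Trials of the same joint at the same time point (three per protocol) are
#' combined by the arithmetic mean of their friction coefficients.
#'
#' @param estimates List of `cof_estimate` objects (warns unless exactly 3).
#' @return A `joint_cof` list with `trial_estimates`, `n_trials`, `mean_mu`.
#' @export
average_trials <- function(estimates) {
  if (inherits(estimates, "cof_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0L)
    jf_error("no trial estimates to average", "config_error")
  stopifnot(all(vapply(estimates, inherits, TRUE, "cof_estimate")))
  if (length(estimates) != 3L)
    warning(sprintf("expected 3 trials per joint, got %d", length(estimates)))
  mus <- vapply(estimates, `[[`, numeric(1), "mu_hat")
  structure(list(trial_estimates = estimates, n_trials = length(estimates),
                 mean_mu = mean(mus)),
            class = "joint_cof")
}

#' @export
print.joint_cof <- function(x, ...) {
  cat(sprintf("Joint CoF: mean mu = %.4g over %d trials\n",
              x$mean_mu, x$n_trials))
  invisible(x)
}

#' Full measurement round trip for a known friction coefficient
#'
#' Simulates a free-oscillation trial at the given Coulomb coefficient,
#' renders the 8-marker frames, recovers the angle series by rigid
#' registration and re-estimates the coefficient via the Stanton decay fit.
#' With zero marker noise this closes to within a fraction of a percent and
#' is the package's core self-consistency check.
#'
#' @param mu True Coulomb coefficient of friction.
#' @param config A [pendulum_config()].
#' @param layout A [marker_layout()].
#' @param noise_sd Marker noise in mm (0 for the noise-free round trip).
#' @param seed Optional RNG seed for the marker noise.
#' @param duration Trial duration in s (`NULL` = automatic).
#' @param min_amplitude Passed to [detect_peaks()].
#' @return A `cof_estimate` whose `mu_hat` is the recovered coefficient.
#' @export
cof_roundtrip <- function(mu, config = pendulum_config(),
                          layout = default_marker_layout(), noise_sd = 0,
                          seed = NULL, duration = NULL,
                          min_amplitude = deg2rad(1)) {
  traj <- simulate_free_oscillation(config, friction_params(mu = mu),
                                    duration = duration)
  frames <- render_markers(traj, layout, noise_sd = noise_sd, seed = seed)
  series <- estimate_angles(frames, layout)
  estimate_trial(series, config, min_amplitude = min_amplitude)
}
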