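#' Recover the pendulum angle from marker frames
#'
#' Per frame, two rigid registrations: (i) the least-squares rigid transform
#' (2-D Kabsch) of the observed base markers onto their reference positions
#' estimates and removes any drift of the whole apparatus; (ii) the
#' drift-corrected arm markers are registered to their equilibrium reference
#' by the closed-form orthogonal Procrustes rotation about the pivot (no
#' translation), whose angle is the pendulum angle for that frame. The
#' recovered series is phase-unwrapped so it is continuous.
#'
#' Frames with fewer than 3 visible arm or base markers are flagged and
#' their angles filled by linear interpolation from neighbouring frames; if
#' more than 5% of frames are flagged, an error is raised.
#'
#' @param frames A `marker_frames` object (see [render_markers()] or
#'   [read_trajectory()]).
#' @param layout The [marker_layout()] giving reference coordinates; defaults
#'   to the layout stored in `frames`.
#' @return An `angle_series` with `times` (s), `angles` (rad, deviation from
#'   equilibrium), per-frame `residual_rms` (mm) of the arm registration,
#'   and `n_interpolated`, the number of frames filled by interpolation.
#' @export
estimate_angles <- function(frames, layout = frames$layout) {
  stopifnot(inherits(layout, "marker_layout"))
  pos <- frames$positions
  nfr <- dim(pos)[1L]
  n_arm <- nrow(layout$arm)
  n_base <- nrow(layout$base)
  arm_ref <- layout$arm
  base_ref <- layout$base
  pivot <- layout$pivot

  # conditioning: arm markers collinear through the pivot leave the
  # perpendicular direction unconstrained under noise
  sv <- svd(arm_ref)$d
  if (sv[2L] / sv[1L] < 1e-8)
    jf_error("conditioning error: arm markers are collinear through the pivot",
             "conditioning_error")

  angles <- rep(NA_real_, nfr)
  resid <- rep(NA_real_, nfr)
  flagged <- logical(nfr)

  for (i in seq_len(nfr)) {
    bo <- pos[i, n_arm + seq_len(n_base), , drop = TRUE]
    ao <- pos[i, seq_len(n_arm), , drop = TRUE]
    b_ok <- stats::complete.cases(bo)
    a_ok <- stats::complete.cases(ao)
    if (sum(b_ok) < 3L || sum(a_ok) < 3L) {
      flagged[i] <- TRUE
      next
    }
    # base drift: rigid transform observed -> reference
    bo_u <- bo[b_ok, , drop = FALSE]
    br_u <- base_ref[b_ok, , drop = FALSE]
    cb_o <- colMeans(bo_u)
    cb_r <- colMeans(br_u)
    X <- sweep(bo_u, 2L, cb_o)
    Y <- sweep(br_u, 2L, cb_r)
    phi <- atan2(sum(X[, 1L] * Y[, 2L] - X[, 2L] * Y[, 1L]),
                 sum(X[, 1L] * Y[, 1L] + X[, 2L] * Y[, 2L]))
    Rd <- rot2(phi)
    # drift-corrected arm markers, pivot-relative
    ao_u <- ao[a_ok, , drop = FALSE]
    corr <- sweep(sweep(ao_u, 2L, cb_o) %*% t(Rd), 2L, cb_r, `+`)
    u <- sweep(corr, 2L, pivot)
    ref <- arm_ref[a_ok, , drop = FALSE]
    # Procrustes rotation about the pivot
    th <- atan2(sum(ref[, 1L] * u[, 2L] - ref[, 2L] * u[, 1L]),
                sum(ref[, 1L] * u[, 1L] + ref[, 2L] * u[, 2L]))
    angles[i] <- th
    res <- u - ref %*% t(rot2(th))
    resid[i] <- sqrt(mean(res^2))
  }

  n_flagged <- sum(flagged)
  if (n_flagged > 0.05 * nfr)
    jf_error(sprintf("%d of %d frames (> 5%%) lack 3 visible arm/base markers",
                     n_flagged, nfr), "missing_data_error")
  angles <- unwrap_angles(angles)
  if (n_flagged > 0L) {
    ok <- !flagged
    angles[flagged] <- stats::approx(frames$times[ok], angles[ok],
                                     xout = frames$times[flagged],
                                     rule = 2)$y
  }

  structure(list(times = frames$times, angles = angles,
                 residual_rms = resid, n_interpolated = n_flagged),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("Angle series: %d frames, range [%.3g, %.3g] deg\n",
              length(x$times), rad2deg(min(x$angles, na.rm = TRUE)),
              rad2deg(max(x$angles, na.rm = TRUE))))
  cat(sprintf("  mean registration residual %.3g mm; %d frames interpolated\n",
              mean(x$residual_rms, na.rm = TRUE), x$n_interpolated))
  invisible(x)
}
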