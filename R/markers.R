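#' Reflective-marker layout
#'
#' Reference coordinates (mm) of the 8 reflective markers: at least 3 (by
#' default 4) rigid to the pendulum arm, given pivot-relative in the
#' equilibrium pose, and at least 3 (by default 4) fixed to the base of the
#' apparatus, given in world coordinates. Fewer than 3 markers on either
#' body would make the angle (or the base drift) unrecoverable robustly and
#' is rejected.
#'
#' @param arm Numeric matrix (>= 3 rows, 2 cols), arm-marker positions in mm
#'   relative to the pivot at equilibrium.
#' @param base Numeric matrix (>= 3 rows, 2 cols), base-marker world
#'   positions in mm.
#' @param pivot Length-2 numeric, world position of the pivot in mm.
#' @return An object of class `marker_layout`.
#' @export
marker_layout <- function(arm, base, pivot = c(0, 0)) {
  arm <- as.matrix(arm); base <- as.matrix(base)
  if (!is.numeric(arm) || ncol(arm) != 2L || nrow(arm) < 3L)
    jf_error("layout error: need >= 3 arm markers (n x 2 matrix, mm)",
             "layout_error")
  if (!is.numeric(base) || ncol(base) != 2L || nrow(base) < 3L)
    jf_error("layout error: need >= 3 base markers (n x 2 matrix, mm)",
             "layout_error")
  stopifnot(length(pivot) == 2L, all(is.finite(arm)), all(is.finite(base)))
  rownames(arm) <- paste0("a", seq_len(nrow(arm)))
  rownames(base) <- paste0("b", seq_len(nrow(base)))
  structure(list(arm = arm, base = base, pivot = as.numeric(pivot)),
            class = "marker_layout")
}

#' Default 8-marker layout: 4 arm markers on the hanging arm, 4 base markers
#' framing the apparatus.
#' @return A [marker_layout()].
#' @export
default_marker_layout <- function() {
  marker_layout(
    arm = rbind(c(-4, -6), c(4, -6), c(-4, -18), c(4, -18)),
    base = rbind(c(-30, -40), c(30, -40), c(-30, 10), c(30, 10)),
    pivot = c(0, 0))
}

marker_names <- function(layout) c(rownames(layout$arm), rownames(layout$base))

#' Render a simulated trajectory as reflective-marker frames
#'
#' For each sampled frame the arm markers are the layout's reference points
#' rotated by that frame's angle about the pivot; base markers are static.
#' Independent isotropic Gaussian noise of standard deviation `noise_sd`
#' (mm) is added to every coordinate.
#'
#' @param traj A `trial_trajectory` (or any list with `times` and `angles`
#'   in radians).
#' @param layout A [marker_layout()].
#' @param noise_sd Marker noise standard deviation in mm (default 0.05).
#' @param seed Optional integer; when given the noise is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return A `marker_frames` object: `times` plus a `[frame, marker, coord]`
#'   array of positions in mm.
#' @export
render_markers <- function(traj, layout = default_marker_layout(),
                           noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(layout, "marker_layout"))
  check_nonnegative(noise_sd, "noise_sd")
  angles <- traj$angles
  nfr <- length(angles)
  nm <- nrow(layout$arm) + nrow(layout$base)
  pos <- array(NA_real_, dim = c(nfr, nm, 2L),
               dimnames = list(NULL, marker_names(layout), c("x", "y")))
  ca <- cos(angles); sa <- sin(angles)
  ax <- layout$arm[, 1L]; ay <- layout$arm[, 2L]
  for (j in seq_len(nrow(layout$arm))) {
    pos[, j, 1L] <- layout$pivot[1L] + ca * ax[j] - sa * ay[j]
    pos[, j, 2L] <- layout$pivot[2L] + sa * ax[j] + ca * ay[j]
  }
  for (j in seq_len(nrow(layout$base))) {
    k <- nrow(layout$arm) + j
    pos[, k, 1L] <- layout$base[j, 1L]
    pos[, k, 2L] <- layout$base[j, 2L]
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(pos), sd = noise_sd))
    pos <- pos + array(noise, dim = dim(pos), dimnames = dimnames(pos))
  }
  structure(list(times = traj$times, positions = pos, layout = layout,
                 noise_sd = noise_sd),
            class = "marker_frames")
}

#' @export
print.marker_frames <- function(x, ...) {
  cat(sprintf("Marker frames: %d frames x %d markers (noise sd %.3g mm)\n",
              dim(x$positions)[1L], dim(x$positions)[2L], x$noise_sd))
  invisible(x)
}
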