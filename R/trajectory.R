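#' Fixed entry-to-target trajectory
#'
#' A straight insertion path defined by an entry point and a target point
#' in the same space. Positions along it are parameterized by the physical
#' drive depth read off a vernier scale or microdrive.
#'
#' @param entry,target Points in one common space.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(entry, target) {
  space <- if (is_point3(entry)) entry$space else
    if (is_point3(target)) target$space else "anatomical"
  check_space(entry, space, "entry"); check_space(target, space, "target")
  e <- as_coords(entry); t <- as_coords(target)
  if (euclidean_norm(t - e) <= 1e-6) {
    stop("entry and target coincide; trajectory undefined", call. = FALSE)
  }
  structure(list(entry = e, target = t, space = space), class = "trajectory")
}

#' @export
print.trajectory <- function(x, digits = 6, ...) {
  cat(sprintf("<trajectory %s> entry (%s) -> target (%s), length %.4g mm\n",
              x$space,
              paste(round(x$entry, digits), collapse = ", "),
              paste(round(x$target, digits), collapse = ", "),
              trajectory_length(x)))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @return `trajectory_length()`: entry-to-target distance in mm.
#' @export
trajectory_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  euclidean_norm(traj$target - traj$entry)
}

#' Drive depth as a fraction of the entry-target distance
#'
#' `f = d_current / d_entry_target`. Values above 1 (overshoot past the
#' target, common with microdrives) are permitted with a warning.
#'
#' @param traj A [trajectory].
#' @param d_current Drive depth from entry, mm; must be nonnegative.
#' @return Dimensionless fraction.
#' @export
depth_fraction <- function(traj, d_current) {
  stopifnot(inherits(traj, "trajectory"), is.finite(d_current))
  if (d_current < 0) {
    stop("drive depth must be nonnegative", call. = FALSE)
  }
  f <- d_current / trajectory_length(traj)
  if (f > 1) {
    warning(sprintf("depth %.3g mm overshoots the target (f = %.4g)",
                    d_current, f), call. = FALSE)
  }
  f
}

#' Point at a fractional position along a trajectory
#'
#' `P = entry + f * (target - entry)`. `f` outside `[0, 1]` extrapolates
#' (with a warning): the geometry does not forbid it and drives overshoot
#' in practice.
#'
#' @param traj A [trajectory].
#' @param f Dimensionless fraction, typically from [depth_fraction()].
#' @return A [point3] in the trajectory's space.
#' @export
point_at_fraction <- function(traj, f) {
  stopifnot(inherits(traj, "trajectory"), is.finite(f))
  if (f < 0 || f > 1) {
    warning(sprintf("fraction %.4g is outside [0, 1]: extrapolating", f),
            call. = FALSE)
  }
  v <- traj$entry + f * (traj$target - traj$entry)
  point3(v[1], v[2], v[3], traj$space)
}

#' Closest point on a trajectory to an arbitrary point
#'
#' Scalar projection of the point onto the unit trajectory direction:
#' useful for asking at what drive depth a measured electrode position
#' sits, and how far off the planned line it is.
#'
#' @param traj A [trajectory].
#' @param p A point in the trajectory's space.
#' @return A list with `depth` (mm from entry along the line, signed) and
#'   `lateral_offset` (perpendicular distance, mm).
#' @export
depth_of_closest_point <- function(traj, p) {
  stopifnot(inherits(traj, "trajectory"))
  check_space(p, traj$space)
  u <- (traj$target - traj$entry) / trajectory_length(traj)
  w <- as_coords(p) - traj$entry
  depth <- sum(w * u)
  lateral <- euclidean_norm(w - depth * u)
  list(depth = depth, lateral_offset = lateral)
}
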