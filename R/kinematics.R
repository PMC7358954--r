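#' Signed trajectory angles
#'
#' The head-stage orientation is described by a sagittal angle `phi`
#' (rotation about the LAT axis, positive when the trajectory leans
#' anterior), a coronal angle `psi` (about the AP axis, positive when it
#' leans right), and an optional axial angle `gamma` (about the VERT axis,
#' e.g. electrode rotation; zero in every printed worked example). Raw
#' frame dial readings are converted to these signed angles by
#' [crw_dials_to_angles()]; some apparatus assemblies mount the arc the
#' other way round, which negates both signed angles
#' (`assembly_flipped`).
#'
#' @param sagittal_phi,coronal_psi,axial_gamma Angles in degrees.
#' @param raw_dials Optional list recording the dial readings the angles
#'   came from, e.g. `list(ring = 51.8, arc = 20.5)`.
#' @param assembly_flipped If `TRUE`, negate both sagittal and coronal
#'   angles (flipped apparatus assembly).
#' @return An object of class `trajectory_angles`.
#' @export
trajectory_angles <- function(sagittal_phi, coronal_psi, axial_gamma = 0,
                              raw_dials = NULL, assembly_flipped = FALSE) {
  stopifnot(is.finite(sagittal_phi), is.finite(coronal_psi),
            is.finite(axial_gamma))
  if (isTRUE(assembly_flipped)) {
    sagittal_phi <- -sagittal_phi
    coronal_psi <- -coronal_psi
  }
  if (abs(sagittal_phi) > 90 || abs(coronal_psi) > 90) {
    warning("trajectory angles beyond +/-90 degrees are not physically ",
            "mountable on an isocentric frame", call. = FALSE)
  }
  structure(list(sagittal_phi = sagittal_phi, coronal_psi = coronal_psi,
                 axial_gamma = axial_gamma, raw_dials = raw_dials),
            class = "trajectory_angles")
}

#' @export
print.trajectory_angles <- function(x, ...) {
  cat(sprintf("<trajectory_angles> sagittal %.4g  coronal %.4g  axial %.4g (deg)\n",
              x$sagittal_phi, x$coronal_psi, x$axial_gamma))
  invisible(x)
}

#' Elemental rotation matrix
#'
#' Rotation about one axis of math order (x = LAT, y = AP, z = VERT), with
#' the sign convention used by the frame equations: the `sin` term above
#' the diagonal is positive, below it negative.
#'
#' @param axis `"x"` (sagittal, about LAT), `"y"` (coronal, about AP), or
#'   `"z"` (axial, about VERT).
#' @param angle Degrees.
#' @return A 3x3 rotation matrix in math order.
#' @export
elemental_rotation <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  a <- angle * pi / 180
  co <- cos(a); si <- sin(a)
  switch(axis,
    x = rbind(c(1, 0, 0),
              c(0, co, si),
              c(0, -si, co)),
    y = rbind(c(co, 0, si),
              c(0, 1, 0),
              c(-si, 0, co)),
    z = rbind(c(co, si, 0),
              c(-si, co, 0),
              c(0, 0, 1)))
}

#' Combined trajectory rotation
#'
#' `R_xy = R_x(phi) %*% R_y(psi)`, optionally extended by the axial
#' rotation to `R_xyz = R_x %*% R_y %*% R_z`. Being a product of
#' rotations, its inverse is its transpose.
#'
#' @param a A [trajectory_angles].
#' @param include_axial Include `R_z(gamma)` (needed for frameless
#'   head-stages that rotate the electrode).
#' @return A 3x3 rotation matrix in math order.
#' @export
compose_trajectory_rotation <- function(a, include_axial = (a$axial_gamma != 0)) {
  stopifnot(inherits(a, "trajectory_angles"))
  R <- elemental_rotation("x", a$sagittal_phi) %*%
       elemental_rotation("y", a$coronal_psi)
  if (include_axial) R <- R %*% elemental_rotation("z", a$axial_gamma)
  R
}

#' Signed angles from CRW dial readings
#'
#' The CRW ring dial is offset 90 degrees from the sagittal angle
#' (`phi = 90 - ring`). The arc dial is unsigned; the coronal angle is
#' positive on a right-sided trajectory and negative on the left.
#'
#' @param ring,arc Dial readings in degrees.
#' @param side `"right"` or `"left"`.
#' @param assembly_flipped Passed through to [trajectory_angles()].
#' @return A [trajectory_angles] with `raw_dials` recorded.
#' @export
crw_dials_to_angles <- function(ring, arc, side = c("right", "left"),
                                assembly_flipped = FALSE) {
  side <- match.arg(side)
  trajectory_angles(
    sagittal_phi = 90 - ring,
    coronal_psi = if (side == "right") arc else -arc,
    raw_dials = list(ring = ring, arc = arc, side = side),
    assembly_flipped = assembly_flipped)
}

#' Head-stage displacement
#'
#' A displacement on the head-stage's own axes: `ap`/`lat` on the XY
#' stage, `vert` along the probe-drive (depth) axis.
#'
#' @param ap,lat,vert Millimetres.
#' @return An object of class `headstage_delta`.
#' @export
headstage_delta <- function(ap, lat, vert) {
  v <- c(ap = as.numeric(ap), lat = as.numeric(lat), vert = as.numeric(vert))
  stopifnot(all(is.finite(v)))
  structure(list(coords = v), class = "headstage_delta")
}

#' @export
print.headstage_delta <- function(x, digits = 6, ...) {
  cat(sprintf("<headstage_delta> AP %.*g  LAT %.*g  VERT %.*g (mm)\n",
              digits, x$coords[1], digits, x$coords[2], digits, x$coords[3]))
  invisible(x)
}

delta_coords <- function(d) {
  if (inherits(d, "headstage_delta")) return(unname(d$coords))
  d <- as.numeric(d)
  stopifnot(length(d) == 3L, all(is.finite(d)))
  d
}

#' Move a frame-space point by a head-stage displacement
#'
#' `X'_n = X'_c + R'_xy %*% delta`: the head-stage displacement, expressed
#' on the rotated head-stage axes, is carried into frame space by the
#' trajectory rotation. Norm-preserving.
#'
#' @param x_frame_current Current frame-space point.
#' @param a A [trajectory_angles].
#' @param d A [headstage_delta] (or numeric `(ap, lat, vert)`).
#' @return The new frame-space [point3].
#' @export
headstage_to_frame_point <- function(x_frame_current, a, d) {
  check_space(x_frame_current, "frame")
  Rxy <- rotation_to_storage_order(compose_trajectory_rotation(a))
  v <- as_coords(x_frame_current) + drop(Rxy %*% delta_coords(d))
  point3(v[1], v[2], v[3], "frame")
}

#' Head-stage displacement between two frame-space points
#'
#' `delta = R'_xy^-1 %*% (X'_t - X'_c)`; the inverse of
#' [headstage_to_frame_point()]. Because `R'_xy` is a rotation, the
#' inverse is the transpose and the displacement norm equals the
#' frame-space distance.
#'
#' @param x_frame_current,x_frame_target Frame-space points.
#' @param a A [trajectory_angles].
#' @return A [headstage_delta].
#' @export
frame_point_to_headstage_delta <- function(x_frame_current, x_frame_target, a) {
  check_space(x_frame_current, "frame"); check_space(x_frame_target, "frame")
  Rxy <- rotation_to_storage_order(compose_trajectory_rotation(a))
  v <- drop(crossprod(Rxy, as_coords(x_frame_target) - as_coords(x_frame_current)))
  headstage_delta(v[1], v[2], v[3])
}

#' Combined head-stage-to-anatomy rotation
#'
#' `W' = R'_(frame-to-anatomy) %*% R'_xy` maps head-stage displacements
#' directly into anatomical displacements, composing the landmark
#' registration with the trajectory rotation.
#'
#' @param reg A `rigid_transform` from [build_3pt_transform()], or `NULL`
#'   for frameless mode, where the angles are anatomical and `W` is just
#'   `R_xyz`.
#' @param a A [trajectory_angles].
#' @return A 3x3 rotation matrix in storage order (AP, LAT, VERT).
#' @export
combined_transform_W <- function(reg, a) {
  Rxy <- rotation_to_storage_order(
    compose_trajectory_rotation(a, include_axial = (a$axial_gamma != 0)))
  if (is.null(reg)) return(Rxy)
  stopifnot(inherits(reg, "rigid_transform"))
  reg$rotation %*% Rxy
}

#' Move an anatomical point by a head-stage displacement
#'
#' `X_n = X_c + W' %*% delta`. With `W` built from a frame registration
#' this is the frame-based workflow; with `W = R_xyz` from anatomical
#' angles it is the frameless one — the same arithmetic either way.
#'
#' @param x_anat_current Current anatomical point.
#' @param W Rotation from [combined_transform_W()] (storage order).
#' @param d A [headstage_delta].
#' @return The new anatomical [point3].
#' @export
headstage_to_anatomy <- function(x_anat_current, W, d) {
  check_space(x_anat_current, "anatomical")
  v <- as_coords(x_anat_current) + drop(W %*% delta_coords(d))
  point3(v[1], v[2], v[3], "anatomical")
}

#' Head-stage adjustment to reach an anatomical target
#'
#' `delta = W'^-1 %*% (X_t - X_c)`: the intraoperative question "how far
#' do I move the stage and drive to get from where the electrode is to
#' where I want it". Norm-preserving inverse of [headstage_to_anatomy()].
#'
#' @param x_anat_current,x_anat_target Anatomical points.
#' @param W Rotation from [combined_transform_W()].
#' @return A [headstage_delta].
#' @export
anatomy_target_to_headstage_delta <- function(x_anat_current, x_anat_target, W) {
  check_space(x_anat_current, "anatomical")
  check_space(x_anat_target, "anatomical")
  v <- drop(crossprod(W, as_coords(x_anat_target) - as_coords(x_anat_current)))
  headstage_delta(v[1], v[2], v[3])
}

#' Trajectory direction in anatomical space
#'
#' Rotates the probe depth axis (math-order `(0, 0, 1)`) by `W'` and
#' reports the anatomical direction plus the coronal (`atan(LAT/VERT)`)
#' and sagittal (`atan(AP/VERT)`) angles in degrees — the angles a
#' planning station prints alongside the frame dials.
#'
#' @param reg A `rigid_transform` (or `NULL` for frameless).
#' @param a A [trajectory_angles].
#' @return A list with `direction` (unit vector, storage order),
#'   `coronal_deg`, `sagittal_deg`.
#' @export
trajectory_direction_anatomy <- function(reg, a) {
  W <- combined_transform_W(reg, a)
  dir <- drop(W %*% c(0, 0, 1))            # depth axis is VERT in both orders
  if (dir[3] <= 0) {
    stop("trajectory is not descending (VERT component <= 0); ",
         "angles undefined", call. = FALSE)
  }
  list(direction = dir,
       coronal_deg = atan(dir[2] / dir[3]) * 180 / pi,
       sagittal_deg = atan(dir[1] / dir[3]) * 180 / pi)
}

#' Decompose a targeting discrepancy
#'
#' Splits a head-stage displacement into the radial component
#' perpendicular to the trajectory (`sqrt(ap^2 + lat^2)`), the depth
#' component along the probe axis (`|vert|`), and the total Euclidean
#' error. A large depth share means the electrode is on the planned line
#' but at the wrong depth.
#'
#' @param d A [headstage_delta].
#' @return A list with `radial`, `depth`, `euclidean` (mm); satisfies
#'   `radial^2 + depth^2 == euclidean^2`.
#' @export
targeting_error <- function(d) {
  v <- delta_coords(d)
  list(radial = sqrt(v[1]^2 + v[2]^2),
       depth = abs(v[3]),
       euclidean = euclidean_norm(v))
}

## Frame-model registry: target-centered frames, their dial origin offsets
## (LAT, AP, VERT as printed in vendor documentation) and displacement
## sign conventions (+1 when the dial increases rightward / anteriorly /
## superiorly). N-localizer dimensions are metadata only.
FRAME_MODELS <- list(
  crw = list(name = "CRW", origin_offset = c(lat = 0, ap = 0, vert = -86),
             axis_signs = c(right = 1, anterior = 1, superior = 1),
             n_localizer_mm = c(height = 189, width = 140)),
  leksell_g = list(name = "Leksell G",
                   origin_offset = c(lat = 100, ap = 100, vert = 160),
                   axis_signs = c(right = -1, anterior = 1, superior = -1),
                   n_localizer_mm = c(height = 120, width = 120)),
  micromar = list(name = "Micromar", origin_offset = c(lat = 0, ap = 0, vert = 0),
                  axis_signs = c(right = 1, anterior = 1, superior = 1),
                  n_localizer_mm = c(height = 140, width = 140)),
  fime = list(name = "FiMe", origin_offset = c(lat = 0, ap = 0, vert = 0),
              axis_signs = c(right = 1, anterior = 1, superior = 1),
              n_localizer_mm = c(height = 160, width = 160)),
  macom = list(name = "Macom", origin_offset = c(lat = 0, ap = 0, vert = 0),
               axis_signs = c(right = 1, anterior = 1, superior = 1),
               n_localizer_mm = c(height = 140, width = 140)),
  zeppelin = list(name = "Zeppelin", origin_offset = c(lat = 0, ap = 0, vert = 0),
                  axis_signs = c(right = 1, anterior = 1, superior = 1),
                  n_localizer_mm = c(height = 140, width = 140))
)

#' Look up a frame model
#'
#' @param name Frame name, case-insensitive (`"CRW"`, `"Leksell G"`, ...).
#' @return An object of class `frame_model`.
#' @export
frame_model <- function(name) {
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(name)))
  fm <- FRAME_MODELS[[key]]
  if (is.null(fm)) {
    stop(sprintf("unknown frame model '%s'; known: %s", name,
                 paste(vapply(FRAME_MODELS, `[[`, "", "name"),
                       collapse = ", ")), call. = FALSE)
  }
  structure(fm, class = "frame_model")
}

#' @rdname frame_model
#' @return `list_frame_models()`: character vector of known model names.
#' @export
list_frame_models <- function() {
  unname(vapply(FRAME_MODELS, `[[`, "", "name"))
}

#' Convert between target-centered and frame-native dial coordinates
#'
#' Frames differ in where their dial origin sits and which dial direction
#' is positive: e.g. the Leksell G origin is right-posterior-superior, so
#' its LAT and VERT dials decrease rightward and superiorly. This applies
#' `native = offset + signs * p` componentwise (offsets given as
#' `(lat, ap, vert)` are reordered to storage order internally).
#'
#' @param fm A [frame_model].
#' @param p A target-centered frame-space point (`(AP, LAT, VERT)`,
#'   + right / + anterior / + superior).
#' @param inverse If `TRUE`, convert frame-native dial coordinates back.
#' @return A [point3] in frame space.
#' @export
apply_frame_model <- function(fm, p, inverse = FALSE) {
  stopifnot(inherits(fm, "frame_model"))
  v <- as_coords(p)
  off <- unname(fm$origin_offset[c("ap", "lat", "vert")])
  sgn <- unname(fm$axis_signs[c("anterior", "right", "superior")])
  w <- if (inverse) (v - off) / sgn else off + sgn * v
  point3(w[1], w[2], w[3], "frame")
}
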