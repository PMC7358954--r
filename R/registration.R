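#' Landmark set for anatomy-frame registration
#'
#' The three-point change of basis needs the anterior commissure (AC),
#' posterior commissure (PC), and one midline point off the AC-PC line —
#' typically on the falx cerebri or a midline ventricular structure — all
#' localized in frame space. The anatomical (mid-commissural) positions of
#' AC and PC are implied by the AC-PC distance; optional extra named pairs
#' feed the least-squares fit.
#'
#' @param ac,pc,falx [point3] objects (or numeric 3-vectors) in one common
#'   space, usually `"frame"`.
#' @param extra Optional named list of additional points in the same space
#'   (used by [fit_affine_landmarks()] callers assembling pairs).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(ac, pc, falx, extra = list()) {
  space <- if (is_point3(ac)) ac$space else "frame"
  for (p in list(ac, pc, falx)) check_space(p, space, "landmark")
  ac <- as_coords(ac); pc <- as_coords(pc); falx <- as_coords(falx)
  if (euclidean_norm(ac - pc) <= 1) {
    stop("AC and PC are less than 1 mm apart; landmarks implausible",
         call. = FALSE)
  }
  v1 <- ac - (ac + pc) / 2
  v2 <- falx - (ac + pc) / 2
  sin_angle <- euclidean_norm(cross3(v1 / euclidean_norm(v1),
                                     v2 / euclidean_norm(v2)))
  if (!is.finite(sin_angle) || sin_angle < 1e-6) {
    stop("midline point is collinear with the AC-PC line; ",
         "cannot define the sagittal plane", call. = FALSE)
  }
  structure(list(ac = ac, pc = pc, falx = falx, space = space,
                 extra = extra),
            class = "landmark_set")
}

#' Midpoint of the commissures
#'
#' The mid-commissural point, the origin of anatomical space, is the
#' componentwise mean of AC and PC.
#'
#' @param ac,pc Points in the same space.
#' @return A [point3] at the midpoint, tagged with the common space.
#' @export
commissural_midpoint <- function(ac, pc) {
  space <- if (is_point3(ac)) ac$space else if (is_point3(pc)) pc$space else "frame"
  check_space(ac, space, "AC"); check_space(pc, space, "PC")
  m <- (as_coords(ac) + as_coords(pc)) / 2
  point3(m[1], m[2], m[3], space)
}

#' AC-PC distance
#'
#' @param ac,pc Points in the same space.
#' @return Euclidean distance in millimetres.
#' @export
acpc_distance <- function(ac, pc) {
  if (is_point3(ac) && is_point3(pc) && ac$space != pc$space) {
    stop("AC and PC must be in the same space", call. = FALSE)
  }
  euclidean_norm(as_coords(ac) - as_coords(pc))
}

#' Three-point rigid anatomy-frame transform
#'
#' Builds the rigid change of basis between frame space and the
#' mid-commissural anatomical space from AC, PC, and a midline (falx)
#' point. In math order (x = LAT, y = AP, z = VERT) the anatomical basis
#' expressed in frame coordinates is: the AP axis is the unit vector from
#' the commissural midpoint to AC; the LAT axis is the normalized cross
#' product of that vector with the midpoint-to-falx vector (order swapped
#' automatically when the falx point lies below the AC-PC line, preserving
#' the right-hand rule); the VERT axis completes the triad. Rows of the
#' resulting rotation are those basis vectors, so the matrix maps
#' frame displacements into anatomy.
#'
#' @param lm A [landmark_set] in frame space.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   (3x3, storage order, frame-to-anatomy), `origin` (the mid-commissural
#'   point in frame coordinates), `falx_below` (whether the cross-product
#'   order was swapped), and space tags.
#' @export
build_3pt_transform <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  pm <- (lm$ac + lm$pc) / 2
  m_ac <- to_math_order(lm$ac)
  m_pm <- to_math_order(pm)
  m_fx <- to_math_order(lm$falx)

  v1 <- m_ac - m_pm
  v2 <- m_fx - m_pm
  v1h <- v1 / euclidean_norm(v1)
  v2h <- v2 / euclidean_norm(v2)

  ## Is the falx point below the AC-PC line? Judge by the VERT (frame z)
  ## sign of its component perpendicular to the line; if below, the
  ## cross-product order is swapped so the basis stays right-handed with
  ## LAT still pointing right.
  perp <- v2 - v1h * sum(v1h * v2)
  falx_below <- perp[3] < 0

  ix <- if (falx_below) cross3(v2h, v1h) else cross3(v1h, v2h)
  nx <- euclidean_norm(ix)
  if (nx < 1e-6) {
    stop("degenerate landmark geometry: falx collinear with AC-PC",
         call. = FALSE)
  }
  ix <- ix / nx
  iy <- v1h
  iz <- cross3(ix, iy)
  iz <- iz / euclidean_norm(iz)

  R_math <- rbind(ix, iy, iz)
  structure(
    list(rotation = unname(rotation_to_storage_order(R_math)),
         origin = pm,
         falx_below = falx_below,
         frame_space = lm$space, anatomy_space = "anatomical"),
    class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, digits = 6, ...) {
  cat(sprintf("<rigid_transform %s <-> %s>\n", x$frame_space, x$anatomy_space))
  cat("rotation (frame -> anatomy, AP/LAT/VERT rows):\n")
  print(round(x$rotation, digits))
  cat("mid-commissural origin in frame space:",
      paste(round(x$origin, digits), collapse = ", "), "\n")
  if (isTRUE(x$falx_below)) {
    cat("note: midline point below the AC-PC line (cross order swapped)\n")
  }
  invisible(x)
}

#' Convert a frame-space point to anatomy
#'
#' `X = R (X' - P_M')`: subtract the mid-commissural origin, rotate into
#' the anatomical basis.
#'
#' @param t A `rigid_transform` from [build_3pt_transform()].
#' @param p A frame-space point.
#' @return A [point3] in anatomical space.
#' @export
frame_to_anatomy <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  check_space(p, t$frame_space)
  v <- drop(t$rotation %*% (as_coords(p) - t$origin))
  point3(v[1], v[2], v[3], t$anatomy_space)
}

#' Convert an anatomical point to frame space
#'
#' `X' = R^-1 X + P_M'`; for a rotation the inverse is the transpose.
#'
#' @inheritParams frame_to_anatomy
#' @param p An anatomical-space point.
#' @return A [point3] in frame space.
#' @export
anatomy_to_frame <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  check_space(p, t$anatomy_space)
  v <- drop(crossprod(t$rotation, as_coords(p))) + t$origin
  point3(v[1], v[2], v[3], t$frame_space)
}

#' Express a rigid registration as an affine transform
#'
#' @param t A `rigid_transform`.
#' @param direction `"anatomy_to_frame"` (the printed 3x4 planning-report
#'   form: linear `R^-1`, translation `P_M'`) or `"frame_to_anatomy"`.
#' @return An [affine_transform].
#' @export
as_affine <- function(t, direction = c("anatomy_to_frame", "frame_to_anatomy")) {
  stopifnot(inherits(t, "rigid_transform"))
  direction <- match.arg(direction)
  if (direction == "anatomy_to_frame") {
    affine_transform(t(t$rotation), t$origin,
                     from_space = t$anatomy_space, to_space = t$frame_space)
  } else {
    affine_transform(t$rotation, -drop(t$rotation %*% t$origin),
                     from_space = t$frame_space, to_space = t$anatomy_space)
  }
}

#' Least-squares affine fit to landmark pairs
#'
#' Fits the 12-parameter map `frame = L %*% anatomy + T` by ordinary least
#' squares, one regression per output coordinate — the classical N-point
#' planning-station conversion. Because nothing constrains `L` to be a
#' rotation, the fitted linear part is in general slightly
#' non-orthonormal; [registration_diagnostics()] reports by how much.
#' `mode = "rigid"` instead solves the orthogonal Procrustes problem
#' (SVD), returning the best orthonormal rotation plus translation.
#'
#' @param anatomy,frame Lists of points (or an n x 3 matrix each), paired
#'   by position; at least 4 non-coplanar pairs for `"affine"`, 3
#'   non-collinear pairs for `"rigid"`.
#' @param mode `"affine"` (default, unconstrained OLS) or `"rigid"`.
#' @return An [affine_transform] (anatomy to frame) with attributes
#'   `diagnostics` ([registration_diagnostics()] of the linear part plus
#'   per-landmark residuals in mm) accessible via `attr(, "diagnostics")`.
#' @export
fit_affine_landmarks <- function(anatomy, frame, mode = c("affine", "rigid")) {
  mode <- match.arg(mode)
  A <- coerce_point_matrix(anatomy)
  Fm <- coerce_point_matrix(frame)
  if (nrow(A) != nrow(Fm)) stop("landmark lists differ in length", call. = FALSE)
  n <- nrow(A)
  min_n <- if (mode == "affine") 4L else 3L
  if (n < min_n) {
    stop(sprintf("need at least %d landmark pairs for mode '%s', got %d",
                 min_n, mode, n), call. = FALSE)
  }

  if (mode == "affine") {
    X <- cbind(A, 1)
    XtX <- crossprod(X)
    if (abs(det(XtX)) < 1e-9 || qr(X)$rank < 4L) {
      stop("landmarks are coplanar or otherwise rank deficient; ",
           "cannot fit an affine map", call. = FALSE)
    }
    B <- solve(XtX, crossprod(X, Fm))      # 4 x 3: rows 1-3 = t(L), row 4 = T
    linear <- t(B[1:3, , drop = FALSE])
    translation <- B[4, ]
  } else {
    ca <- colMeans(A); cf <- colMeans(Fm)
    H <- crossprod(A - matrix(ca, n, 3, byrow = TRUE),
                   Fm - matrix(cf, n, 3, byrow = TRUE))
    if (qr(H)$rank < 2L) {
      stop("landmarks are collinear; cannot fit a rigid map", call. = FALSE)
    }
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    Rot <- sv$v %*% D %*% t(sv$u)          # anatomy -> frame rotation
    linear <- Rot
    translation <- cf - drop(Rot %*% ca)
  }

  t_af <- affine_transform(linear, translation,
                           from_space = "anatomical", to_space = "frame")
  fitted <- A %*% t(linear) + matrix(translation, n, 3, byrow = TRUE)
  resid <- sqrt(rowSums((Fm - fitted)^2))
  diag <- registration_diagnostics(linear)
  diag$residuals_mm <- resid
  attr(t_af, "diagnostics") <- diag
  t_af
}

coerce_point_matrix <- function(pts) {
  if (is.matrix(pts)) {
    stopifnot(ncol(pts) == 3L)
    return(unname(pts))
  }
  do.call(rbind, lapply(pts, as_coords))
}

#' Orthonormality and orthogonality diagnostics of a linear map
#'
#' Planning reports quality-check a fitted 3x3 conversion matrix by an
#' orthonormality value per row — the squared row norm, which printed
#' reports list (1 for a rigid map; e.g. 1.000711 for a least-squares
#' fit) — and the pairwise dot products between rows (0 for a rigid
#' map). Rows correspond to the AP, LAT, VERT output axes in storage
#' order.
#'
#' @param linear A 3x3 matrix, or an [affine_transform] / `rigid_transform`.
#' @return A list with `row_norms` (squared norms, named AP/LAT/VERT) and
#'   `pairwise_dots` (named `AP-LAT`, `LAT-VERT`, `AP-VERT`).
#' @export
registration_diagnostics <- function(linear) {
  if (inherits(linear, "affine_transform")) linear <- linear$linear
  if (inherits(linear, "rigid_transform")) linear <- t(linear$rotation)
  linear <- as.matrix(linear)
  stopifnot(all(dim(linear) == c(3L, 3L)))
  norms <- rowSums(linear^2)
  names(norms) <- c("AP", "LAT", "VERT")
  dots <- c(`AP-LAT`  = sum(linear[1, ] * linear[2, ]),
            `LAT-VERT` = sum(linear[2, ] * linear[3, ]),
            `AP-VERT` = sum(linear[1, ] * linear[3, ]))
  list(row_norms = norms, pairwise_dots = dots)
}
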