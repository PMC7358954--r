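#' @keywords internal
"_PACKAGE"

## Coordinate spaces recognized throughout the package.
SPACES <- c("anatomical", "frame", "headstage", "atlas_world")

#' Millimetre point in a tagged coordinate space
#'
#' Every coordinate in the package is stored in `(AP, LAT, VERT)` order —
#' antero-posterior (+ anterior), lateral (+ right), vertical (+ superior) —
#' the order in which surgical planning stations and frame vernier scales
#' list them. The `space` tag records which coordinate system the numbers
#' live in and is only changed by an explicit transform.
#'
#' @param ap,lat,vert Coordinates in millimetres; must be finite.
#' @param space One of `"anatomical"` (mid-commissural, origin at the
#'   midpoint of the AC-PC segment), `"frame"` (stereotactic frame),
#'   `"headstage"` (arc/XY-stage platform), `"atlas_world"`.
#' @return An object of class `point3`.
#' @examples
#' point3(-3, 11.5, -3, "anatomical")
#' @export
point3 <- function(ap, lat, vert, space = "anatomical") {
  v <- c(ap = as.numeric(ap), lat = as.numeric(lat), vert = as.numeric(vert))
  if (!all(is.finite(v))) {
    stop("point3 components must be finite, got (",
         paste(v, collapse = ", "), ")", call. = FALSE)
  }
  space <- match.arg(space, SPACES)
  structure(list(coords = v, space = space), class = "point3")
}

#' @export
print.point3 <- function(x, digits = 6, ...) {
  cat(sprintf("<point3 %s> AP %.*g  LAT %.*g  VERT %.*g\n",
              x$space, digits, x$coords[1], digits, x$coords[2],
              digits, x$coords[3]))
  invisible(x)
}

#' @export
as.double.point3 <- function(x, ...) unname(x$coords)

is_point3 <- function(x) inherits(x, "point3")

## Accept either a point3 or a bare length-3 numeric; returns unnamed numeric.
as_coords <- function(p) {
  if (is_point3(p)) return(unname(p$coords))
  p <- as.numeric(p)
  stopifnot(length(p) == 3L, all(is.finite(p)))
  p
}

check_space <- function(p, space, what = "point") {
  if (is_point3(p) && !is.null(space) && p$space != space) {
    stop(sprintf("%s is tagged '%s' but '%s' was required",
                 what, p$space, space), call. = FALSE)
  }
  invisible(TRUE)
}

## Permutation between storage order (ap, lat, vert) and math order
## (x = lat, y = ap, z = vert). Self-inverse: swapping the first two axes.
MATH_PERM <- rbind(c(0, 1, 0),
                   c(1, 0, 0),
                   c(0, 0, 1))

#' Convert between storage order and rotation-math order
#'
#' Tables and case files list coordinates as `(AP, LAT, VERT)`; the
#' elemental rotation matrices are written for axes `x = LAT`, `y = AP`,
#' `z = VERT` (the right-anterior-superior convention). These helpers
#' permute between the two orders; they never scale.
#'
#' @param p A [point3] or bare numeric 3-vector in `(AP, LAT, VERT)` order.
#' @return `to_math_order()`: numeric `(LAT, AP, VERT)` vector.
#' @examples
#' to_math_order(c(1, 2, 3)) # 2 1 3
#' @export
to_math_order <- function(p) {
  v <- as_coords(p)
  c(v[2], v[1], v[3])
}

#' @rdname to_math_order
#' @param v Numeric 3-vector in math `(LAT, AP, VERT)` order.
#' @param space Space tag for the returned point.
#' @return `from_math_order()`: a [point3] in storage order.
#' @export
from_math_order <- function(v, space = "anatomical") {
  v <- as.numeric(v)
  stopifnot(length(v) == 3L)
  point3(v[2], v[1], v[3], space)
}

## A rotation matrix expressed in math order, re-expressed in storage order
## (and vice versa; the conjugating permutation is self-inverse).
rotation_to_storage_order <- function(R_math) MATH_PERM %*% R_math %*% MATH_PERM

euclidean_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Check a matrix for rotation-matrix structure
#'
#' @param M A 3x3 matrix.
#' @param tol Tolerance on `M %*% t(M) - I` and on `det(M) - 1`.
#' @return `TRUE` if orthonormal with determinant +1 within `tol`.
#' @export
is_rotation_matrix <- function(M, tol = 1e-10) {
  is.matrix(M) && all(dim(M) == c(3L, 3L)) &&
    max(abs(M %*% t(M) - diag(3))) < tol &&
    abs(det(M) - 1) < tol
}
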