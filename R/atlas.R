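#' Plane in atlas-world coordinates
#'
#' The implicit plane `lambda*x + mu*y + kappa*z + sigma = 0`, stored with
#' a unit normal (`sigma` rescaled to match) for numerical conditioning;
#' distances then drop the normalizing denominator. Coordinates here are
#' storage order (AP, LAT, VERT) like everywhere else — the algebra is
#' order-agnostic.
#'
#' @param normal Length-3 normal vector `(lambda, mu, kappa)`; need not be
#'   unit length.
#' @param offset Scalar `sigma` on the same scale as `normal`.
#' @return An object of class `plane` with unit `normal` and rescaled
#'   `offset`.
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3L, all(is.finite(normal)), is.finite(offset))
  n <- euclidean_norm(normal)
  if (n <= 0) stop("plane normal must be nonzero", call. = FALSE)
  structure(list(normal = normal / n, offset = offset / n), class = "plane")
}

#' Plane through three points
#'
#' Normal is the cross product of the two edge vectors from the first
#' point; the offset is solved so all three points satisfy the plane
#' equation.
#'
#' @param P,Q,R Non-collinear points (any space; typically atlas world).
#' @return A [plane].
#' @export
plane_from_points <- function(P, Q, R) {
  P <- as_coords(P); Q <- as_coords(Q); R <- as_coords(R)
  n <- cross3(Q - P, R - P)
  if (euclidean_norm(n) < 1e-9 * max(euclidean_norm(Q - P),
                                     euclidean_norm(R - P), 1)) {
    stop("points are collinear; plane undefined", call. = FALSE)
  }
  plane(n, -sum(n * P))
}

#' Distance from a point to a plane
#'
#' `zeta = |lambda*Ex + mu*Ey + kappa*Ez + sigma|` with a unit normal.
#'
#' @param pl A [plane].
#' @param E A point.
#' @return Nonnegative distance in mm.
#' @export
point_plane_distance <- function(pl, E) {
  stopifnot(inherits(pl, "plane"))
  abs(sum(pl$normal * as_coords(E)) + pl$offset)
}

#' Orthogonal projection of a point onto a plane
#'
#' Solves the signed multiple `b` of the normal that carries the point
#' into the plane, then steps along the normal: `X_p = E + b * normal`.
#'
#' @param pl A [plane].
#' @param E A point ([point3] or numeric); the space tag, if any, is kept.
#' @return The projected [point3].
#' @export
project_point_to_plane <- function(pl, E) {
  stopifnot(inherits(pl, "plane"))
  space <- if (is_point3(E)) E$space else "atlas_world"
  v <- as_coords(E)
  b <- -(sum(pl$normal * v) + pl$offset)   # unit normal: denominator is 1
  w <- v + b * pl$normal
  point3(w[1], w[2], w[3], space)
}

#' Atlas slice: plane plus 3D-to-2D screen calibration
#'
#' An atlas section is a plane in world millimetres together with three
#' anchor pairs tying world positions to on-screen pixel coordinates. The
#' 3x3 conversion matrix `M` satisfying `[U V 1] %*% M = [x y z]` for the
#' anchors is solved lazily on first use.
#'
#' @param id Slice identifier (number or string); used for deterministic
#'   tie-breaking in [closest_slice()].
#' @param plane A [plane], or `NULL` to derive it from the world anchors.
#' @param anchors_world 3x3 matrix, one world anchor per row
#'   (AP, LAT, VERT).
#' @param anchors_screen 3x2 matrix, matching `(U, V)` pixel rows.
#' @param image_path Optional path to the slice image (metadata only).
#' @return An object of class `atlas_slice`.
#' @export
atlas_slice <- function(id, plane = NULL, anchors_world, anchors_screen,
                        image_path = NULL) {
  anchors_world <- as.matrix(anchors_world)
  anchors_screen <- as.matrix(anchors_screen)
  stopifnot(all(dim(anchors_world) == c(3L, 3L)),
            all(dim(anchors_screen) == c(3L, 2L)),
            all(is.finite(anchors_world)), all(is.finite(anchors_screen)))
  if (is.null(plane)) {
    plane <- plane_from_points(anchors_world[1, ], anchors_world[2, ],
                               anchors_world[3, ])
  }
  stopifnot(inherits(plane, "plane"))
  for (i in 1:3) {
    if (point_plane_distance(plane, anchors_world[i, ]) > 1e-6) {
      stop(sprintf("world anchor %d is off the slice plane", i),
           call. = FALSE)
    }
  }
  if (abs(det(cbind(anchors_screen, 1))) < 1e-9) {
    stop("screen anchors are collinear; calibration impossible",
         call. = FALSE)
  }
  structure(list(id = id, plane = plane,
                 anchors_world = unname(anchors_world),
                 anchors_screen = unname(anchors_screen),
                 screen_matrix = NULL, image_path = image_path),
            class = "atlas_slice")
}

#' Solve the slice's screen conversion matrix
#'
#' `M = [U V 1]^-1 %*% [x y z]` over the three anchors. The result maps
#' homogeneous screen rows to world rows; its inverse gives world to
#' screen. `M` is singular when the slice has a zero world coordinate in a
#' dimension (e.g. an axial section at VERT = 0); [world_to_screen()]
#' then falls back to an in-plane 2D solve.
#'
#' @param slice An [atlas_slice].
#' @return The slice with `screen_matrix` filled in (returned invisibly
#'   when already solved).
#' @export
solve_screen_matrix <- function(slice) {
  stopifnot(inherits(slice, "atlas_slice"))
  if (!is.null(slice$screen_matrix)) return(slice)
  U <- cbind(slice$anchors_screen, 1)
  slice$screen_matrix <- solve(U, slice$anchors_world)
  slice
}

## In-plane orthonormal basis fallback for world<->screen when M is
## singular: express anchors in 2D plane coordinates, solve the 2D affine
## anchor->screen map. Degrades to exactly the matrix path when M exists.
plane_basis_2d <- function(slice) {
  O <- slice$anchors_world[1, ]
  e1 <- slice$anchors_world[2, ] - O
  e1 <- e1 / euclidean_norm(e1)
  n <- slice$plane$normal
  e2 <- cross3(n, e1)
  list(origin = O, e1 = e1, e2 = e2)
}

fallback_maps <- function(slice) {
  b <- plane_basis_2d(slice)
  P2 <- t(apply(slice$anchors_world, 1, function(w) {
    d <- w - b$origin
    c(sum(d * b$e1), sum(d * b$e2))
  }))
  A_plane <- cbind(P2, 1)                 # 3x3, plane coords homogeneous
  A_screen <- cbind(slice$anchors_screen, 1)
  ## screen -> plane-2D and back
  M_s2p <- solve(A_screen, P2)            # [U V 1] %*% M_s2p = [p q]
  M_p2s <- solve(A_plane, slice$anchors_screen)
  list(basis = b, screen_to_plane = M_s2p, plane_to_screen = M_p2s)
}

#' World point to screen coordinates
#'
#' Applies the inverse of the screen matrix: `[U V 1] = [x y z] %*% M^-1`.
#' If `M` is singular (a slice with zeros in one world dimension), falls
#' back to a 2D affine solve in an in-plane orthonormal basis, which
#' agrees with the matrix path whenever both are defined.
#'
#' @param slice An [atlas_slice].
#' @param X_p A point on (or near) the slice plane; it is projected onto
#'   the plane first if off it.
#' @return Named numeric `c(U = , V = )` in screen pixels.
#' @export
world_to_screen <- function(slice, X_p) {
  stopifnot(inherits(slice, "atlas_slice"))
  slice <- solve_screen_matrix(slice)
  x <- as_coords(project_point_to_plane(slice$plane, X_p))
  M <- slice$screen_matrix
  if (abs(det(M)) > 1e-9) {
    uv1 <- drop(x %*% solve(M))
    if (abs(uv1[3] - 1) > 1e-6) {
      stop("screen mapping produced a non-unit homogeneous coordinate",
           call. = FALSE)
    }
    return(c(U = uv1[1], V = uv1[2]))
  }
  fb <- fallback_maps(slice)
  d <- x - fb$basis$origin
  pq <- c(sum(d * fb$basis$e1), sum(d * fb$basis$e2))
  uv <- drop(c(pq, 1) %*% fb$plane_to_screen)
  c(U = uv[1], V = uv[2])
}

#' Screen coordinates to a world point
#'
#' `[x y z] = [U V 1] %*% M`; with a singular `M`, routes through the 2D
#' in-plane basis instead. The result always lies on the slice plane.
#'
#' @param slice An [atlas_slice].
#' @param U,V Screen pixel coordinates.
#' @return A [point3] in atlas-world space.
#' @export
screen_to_world <- function(slice, U, V) {
  stopifnot(inherits(slice, "atlas_slice"), is.finite(U), is.finite(V))
  slice <- solve_screen_matrix(slice)
  M <- slice$screen_matrix
  if (abs(det(M)) > 1e-9) {
    w <- drop(c(U, V, 1) %*% M)
  } else {
    fb <- fallback_maps(slice)
    pq <- drop(c(U, V, 1) %*% fb$screen_to_plane)
    w <- fb$basis$origin + pq[1] * fb$basis$e1 + pq[2] * fb$basis$e2
  }
  point3(w[1], w[2], w[3], "atlas_world")
}

#' Closest slice in a stack to a point
#'
#' Evaluates the point-to-plane distance for every slice and returns the
#' argmin, its projection of the point, and the distance. Ties go to the
#' slice appearing first in stack order (deterministic).
#'
#' @param stack List of [atlas_slice] objects.
#' @param E The query point.
#' @return A list with `slice`, `projected` ([point3]), `distance` (mm).
#' @export
closest_slice <- function(stack, E) {
  if (length(stack) == 0L) stop("empty slice stack", call. = FALSE)
  zetas <- vapply(stack, function(s) point_plane_distance(s$plane, E),
                  numeric(1))
  i <- which.min(zetas)                   # which.min takes the first tie
  best <- stack[[i]]
  list(slice = best,
       projected = project_point_to_plane(best$plane, E),
       distance = zetas[i])
}

#' Parametric line
#'
#' `X(q) = point + q * direction`, the form a planned trajectory takes for
#' line-plane intersection with an atlas section.
#'
#' @param point Length-3 numeric or [point3]: a point on the line.
#' @param direction Length-3 numeric: direction, mm (need not be unit).
#' @return An object of class `parametric_line`.
#' @export
parametric_line <- function(point, direction) {
  point <- as_coords(point)
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L, all(is.finite(direction)))
  if (euclidean_norm(direction) <= 1e-9) {
    stop("line direction must be nonzero", call. = FALSE)
  }
  structure(list(point = point, direction = direction),
            class = "parametric_line")
}

#' Intersection of a line and a plane
#'
#' Substitutes the parametric line into the plane equation and solves for
#' the parameter: `X_p = X_1 - d * (n . X_1 + sigma) / (n . d)`.
#'
#' @param line A [parametric_line].
#' @param pl A [plane].
#' @return The intersection [point3] (atlas-world tagged).
#' @export
line_plane_intersection <- function(line, pl) {
  stopifnot(inherits(line, "parametric_line"), inherits(pl, "plane"))
  denom <- sum(pl$normal * line$direction)
  num <- sum(pl$normal * line$point) + pl$offset
  if (abs(denom) <= 1e-9) {
    if (abs(num) <= 1e-9) {
      stop("line lies in the plane: infinitely many intersections",
           call. = FALSE)
    }
    stop("line is parallel to the plane: no intersection", call. = FALSE)
  }
  w <- line$point - line$direction * (num / denom)
  point3(w[1], w[2], w[3], "atlas_world")
}

#' AP-axis scaling between patient and atlas
#'
#' Normalizes the antero-posterior coordinate by the ratio of atlas to
#' patient AC-PC distance, anchored at the mid-commissural origin
#' (AP = 0 is fixed; AC and PC land on the atlas commissures). LAT and
#' VERT are untouched — a deliberately simple one-axis correction that
#' works well for basal-ganglia targets.
#'
#' @param p An anatomical point.
#' @param acpc_patient,acpc_atlas AC-PC distances in mm; both positive.
#' @return The scaled [point3] (same space tag).
#' @export
ap_scale_to_atlas <- function(p, acpc_patient, acpc_atlas) {
  stopifnot(is.finite(acpc_patient), is.finite(acpc_atlas))
  if (acpc_patient <= 0 || acpc_atlas <= 0) {
    stop("AC-PC distances must be positive", call. = FALSE)
  }
  v <- as_coords(p)
  out <- point3(v[1] * acpc_atlas / acpc_patient, v[2], v[3],
                if (is_point3(p)) p$space else "anatomical")
  out
}

#' Map a batch of points onto a slice stack
#'
#' For each point: closest slice, projection, screen coordinates. This is
#' the bulk operation used to review intraoperative (kinesthetic) point
#' clouds on an atlas. Per-point failures are recorded in the `error`
#' column rather than aborting the batch.
#'
#' @param points List of points (or an n x 3 matrix).
#' @param stack List of [atlas_slice] objects.
#' @return A data.frame with one row per input point: `slice_id`, `U`,
#'   `V`, `zeta` (distance to the chosen slice, mm), projected world
#'   coordinates `ap`/`lat`/`vert`, and `error` (NA when successful).
#' @export
map_points_to_stack <- function(points, stack) {
  if (length(stack) == 0L) stop("empty slice stack", call. = FALSE)
  if (is.matrix(points)) points <- asplit(points, 1)
  rows <- lapply(points, function(p) {
    tryCatch({
      hit <- closest_slice(stack, p)
      uv <- world_to_screen(hit$slice, hit$projected)
      w <- as_coords(hit$projected)
      data.frame(slice_id = as.character(hit$slice$id),
                 U = uv[["U"]], V = uv[["V"]], zeta = hit$distance,
                 ap = w[1], lat = w[2], vert = w[3],
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(slice_id = NA_character_, U = NA_real_, V = NA_real_,
                 zeta = NA_real_, ap = NA_real_, lat = NA_real_,
                 vert = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic axial atlas stack
#'
#' Builds a stack of axial slices at uniform VERT spacing with identity
#' anchor calibration (screen pixels equal world AP/LAT millimetres).
#' This emulates the sectioning geometry of a histological atlas for
#' tests and examples; it carries no atlas imagery.
#'
#' @param verts VERT positions of the slices, mm (default: multiples of
#'   0.9 mm from -5.4 to 5.4, the sectioning interval of a standard
#'   histological stack).
#' @param anchor_span Half-width of the anchor triangle, mm.
#' @return List of [atlas_slice] objects, ordered as `verts`.
#' @export
synthetic_axial_stack <- function(verts = seq(-5.4, 5.4, by = 0.9),
                                  anchor_span = 50) {
  lapply(verts, function(z) {
    aw <- rbind(c(0, 0, z),
                c(anchor_span, 0, z),
                c(0, anchor_span, z))
    as_ <- rbind(c(0, 0),
                 c(anchor_span, 0),
                 c(0, anchor_span))
    atlas_slice(id = sprintf("axial_%+.1f", z),
                anchors_world = aw, anchors_screen = as_)
  })
}
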