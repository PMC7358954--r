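#' General affine transform between coordinate spaces
#'
#' The affine contract `X = L %*% X' + T` underlies every conversion in the
#' package: rigid change-of-basis transforms built from landmarks, the
#' unconstrained least-squares landmark fit, and the atlas screen maps.
#' For the rigid frame conversions the linear part is orthonormal and no
#' scaling is applied (all spaces are in millimetres); the least-squares
#' fit may carry slight non-orthonormality, which is what the
#' [registration_diagnostics()] report quantifies.
#'
#' The linear part and translation are stored in `(AP, LAT, VERT)` order,
#' matching the printed 3x4 matrix convention of planning reports.
#'
#' @param linear 3x3 matrix (storage order); must be invertible.
#' @param translation Length-3 numeric, millimetres.
#' @param from_space,to_space Space tags (see [point3]).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear, translation,
                             from_space = "anatomical", to_space = "frame") {
  linear <- as.matrix(linear)
  stopifnot(all(dim(linear) == c(3L, 3L)), all(is.finite(linear)))
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  if (abs(det(linear)) <= 1e-9) {
    stop("affine linear part is singular (|det| <= 1e-9)", call. = FALSE)
  }
  structure(
    list(linear = unname(linear), translation = unname(translation),
         from_space = match.arg(from_space, SPACES),
         to_space = match.arg(to_space, SPACES)),
    class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, digits = 6, ...) {
  cat(sprintf("<affine_transform %s -> %s>\n", x$from_space, x$to_space))
  m <- cbind(x$linear, x$translation)
  dimnames(m) <- list(c("AP", "LAT", "VERT"),
                      c("AP", "LAT", "VERT", "transl"))
  print(round(m, digits))
  invisible(x)
}

#' Apply an affine transform to a point
#'
#' @param t An [affine_transform].
#' @param p A [point3] tagged with `t$from_space`, or a bare numeric
#'   3-vector (assumed to be in the correct space).
#' @return A [point3] tagged with `t$to_space`.
#' @export
apply_affine <- function(t, p) {
  stopifnot(inherits(t, "affine_transform"))
  check_space(p, t$from_space)
  v <- drop(t$linear %*% as_coords(p)) + t$translation
  point3(v[1], v[2], v[3], t$to_space)
}

#' Invert an affine transform
#'
#' Returns the composed inverse: linear part `L^-1`, translation
#' `-L^-1 %*% T`, with the space tags swapped.
#'
#' @param t An [affine_transform].
#' @return The inverse [affine_transform].
#' @export
invert_affine <- function(t) {
  stopifnot(inherits(t, "affine_transform"))
  Linv <- solve(t$linear)
  affine_transform(Linv, -drop(Linv %*% t$translation),
                   from_space = t$to_space, to_space = t$from_space)
}
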