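#' Rigid transforms
#'
#' A rigid (proper orthogonal) transform `p -> R p + t` in mm. Used for
#' phantom poses, misalignment of point clouds, and ICP results.
#'
#' @param rotation 3 x 3 orthonormal matrix with `det = +1`.
#' @param translation numeric length-3 (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop("`rotation` must be a finite 3 x 3 matrix", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be a proper rotation (det = +1)", call. = FALSE)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("`translation` must be 3 finite values (mm)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat("rigid_transform: rotation", signif(ang, 4), "deg, translation (",
      paste(signif(x$translation, 4), collapse = ", "), ") mm\n")
  invisible(x)
}

#' Rotation about an axis
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' Maps every point `p` to `R p + t`. This is how phantom point clouds are
#' misaligned to create registration test cases.
#'
#' @param points N x 3 matrix (mm).
#' @param transform a [rigid_transform].
#' @return N x 3 matrix of transformed points.
#' @export
apply_rigid <- function(points, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  out <- points %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b,transform [rigid_transform] objects.
#' @return A [rigid_transform].
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}
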