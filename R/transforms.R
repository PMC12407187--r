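#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation (3-vector, Angstrom). Transforms
#' compose associatively and every transform has an inverse.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric 3-vector, Angstrom.
#' @param tol Orthonormality tolerance.
#' @return A `rigid_transform` object.
#' @examples
#' t1 <- rot_z(72)
#' t2 <- transform_compose(t1, t1)
#' rotation_angle_about_axis(t2, c(0, 0, 1))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-8) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3) {
    abort("rigid_transform needs a 3x3 rotation and a length-3 translation")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    abort("rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > tol) {
    abort("rotation matrix is not a proper rotation (det != +1)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform()

#' Elementary rotations and translations
#'
#' `rot_x()`, `rot_y()` and `rot_z()` build rotations about the coordinate
#' axes; `translation()` builds a pure translation.
#'
#' @param deg Rotation angle in degrees.
#' @name elementary-transforms
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg)
  rigid_transform(matrix(c(cos(a), sin(a), 0,
                           -sin(a), cos(a), 0,
                           0, 0, 1), 3, 3))
}

#' @rdname elementary-transforms
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg)
  rigid_transform(matrix(c(1, 0, 0,
                           0, cos(a), sin(a),
                           0, -sin(a), cos(a)), 3, 3))
}

#' @rdname elementary-transforms
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg)
  rigid_transform(matrix(c(cos(a), 0, -sin(a),
                           0, 1, 0,
                           sin(a), 0, cos(a)), 3, 3))
}

#' @rdname elementary-transforms
#' @param v Translation 3-vector, Angstrom.
#' @export
translation <- function(v) rigid_transform(diag(3), v)

#' Compose transforms
#'
#' `transform_compose(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`.
#'
#' @param a,b Rigid transforms.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a transform
#' @param t A rigid transform.
#' @export
transform_inverse <- function(t) {
  rt <- t(t$rotation)
  rigid_transform(rt, as.numeric(-rt %*% t$translation))
}

#' Apply a rigid transform to a structure or coordinate matrix
#'
#' Every atom position p becomes `rotation %*% p + translation`. All pairwise
#' intra-structure distances are preserved (isometry).
#'
#' @param s A structure or an n x 3 coordinate matrix.
#' @param t A rigid transform.
#' @return The transformed structure (same class as the input).
#' @export
apply_transform <- function(s, t) {
  if (!inherits(t, "rigid_transform")) {
    t <- rigid_transform(t$rotation, t$translation)
  }
  if (is.matrix(s)) {
    return(sweep(s %*% t(t$rotation), 2, -t$translation))
  }
  xyz <- cbind(s$x, s$y, s$z) %*% t(t$rotation)
  s$x <- xyz[, 1] + t$translation[1]
  s$y <- xyz[, 2] + t$translation[2]
  s$z <- xyz[, 3] + t$translation[3]
  s
}

#' Least-squares superposition (Kabsch)
#'
#' Finds the rigid transform minimizing the root-mean-square deviation
#' between two coordinate sets with positional correspondence, using the
#' closed-form SVD solution. Reflections are rejected by forcing the
#' determinant of the recovered rotation to +1.
#'
#' @param mobile,target n x 3 coordinate matrices (or structures, in which
#'   case CA coordinates are used), n >= 3.
#' @return A list with elements `transform` (the rigid transform taking
#'   `mobile` onto `target`) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target) {
  if (is_structure(mobile)) mobile <- ca_coords(mobile)
  if (is_structure(target)) target <- ca_coords(target)
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) {
    abort("superpose: point counts differ")
  }
  n <- nrow(mobile)
  if (n < 3) abort("superpose needs at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  a <- sweep(mobile, 2, cm); b <- sweep(target, 2, ct)
  # collinearity check: second singular value of the centred target set
  if (svd(b, nu = 0, nv = 0)$d[2] < 1e-8 || svd(a, nu = 0, nv = 0)$d[2] < 1e-8) {
    abort("superpose: degenerate (collinear) point set")
  }
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.numeric(rot %*% cm)
  tf <- rigid_transform(rot, tr)
  moved <- apply_transform(mobile, tf)
  list(transform = tf, rmsd = rmsd(moved, target))
}

#' Root-mean-square deviation between corresponding coordinate sets
#' @param a,b n x 3 coordinate matrices or structures.
#' @export
rmsd <- function(a, b) {
  if (is_structure(a)) a <- ca_coords(a)
  if (is_structure(b)) b <- ca_coords(b)
  if (nrow(a) != nrow(b)) abort("rmsd: point counts differ")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Rotation angle about a given axis
#'
#' Returns the rotation angle of a transform's rotation component about a
#' given axis, in degrees within `[0, 360)`. Errors if the transform's
#' rotation axis is not parallel to the requested axis.
#'
#' @param t A rigid transform.
#' @param axis Unit 3-vector.
#' @param tol Axis-parallelism tolerance.
#' @export
rotation_angle_about_axis <- function(t, axis, tol = 1e-6) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) abort("axis must be unit-norm")
  r <- t$rotation
  cos_t <- (sum(diag(r)) - 1) / 2
  cos_t <- min(1, max(-1, cos_t))
  skew <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) / 2
  sin_t <- sum(skew * axis)
  ang <- atan2(sin_t, cos_t)
  # verify the rotation really is about `axis`: axis must be a fixed vector
  resid <- max(abs(as.numeric(r %*% axis) - axis))
  if (resid > tol) {
    abort("transform rotation axis is not parallel to the requested axis")
  }
  # off-axis skew components must vanish too (guards against mixed rotations)
  if (sqrt(sum((skew - sin_t * axis)^2)) > tol) {
    abort("transform rotation axis is not parallel to the requested axis")
  }
  deg <- rad2deg(ang) %% 360
  if (deg >= 360) deg <- 0
  deg
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- tryCatch(
    round(rad2deg(acos(min(1, max(-1, (sum(diag(x$rotation)) - 1) / 2)))), 3),
    error = function(e) NA_real_)
  cat(sprintf("<rigid_transform: rotation %s deg, translation (%.2f, %.2f, %.2f)>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}
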