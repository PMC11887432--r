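# Rigid-body poses as position + unit quaternion, with the handful of
# quaternion operations the geometry layer needs.

#' Unit quaternion
#'
#' @param w,x,y,z components; the quaternion is validated to unit norm
#'   (tolerance 1e-12) unless `normalize = TRUE`.
#' @param normalize divide by the norm instead of erroring.
#' @return Numeric vector of class `pt_quat`.
#' @export
quaternion <- function(w = 1, x = 0, y = 0, z = 0, normalize = FALSE) {
  q <- c(w, x, y, z)
  nrm <- sqrt(sum(q^2))
  if (normalize) {
    if (nrm == 0) stop("cannot normalize a zero quaternion", call. = FALSE)
    q <- q / nrm
  } else if (abs(nrm - 1) > 1e-12) {
    stop("quaternion must have unit norm (tolerance 1e-12)", call. = FALSE)
  }
  structure(q, class = "pt_quat")
}

#' Quaternion from an axis-angle rotation
#'
#' @param axis 3-vector (normalized internally).
#' @param angle rotation angle in radians.
#' @return A `pt_quat`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  quaternion(cos(angle / 2), axis[1] * sin(angle / 2),
             axis[2] * sin(angle / 2), axis[3] * sin(angle / 2))
}

#' Quaternion product (composition of rotations)
#'
#' `quat_multiply(q1, q2)` rotates first by `q2`, then by `q1`, matching
#' rotation-matrix composition `R(q1) %*% R(q2)`.
#'
#' @param q1,q2 `pt_quat` objects.
#' @return A `pt_quat`.
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; v1 <- q1[2:4]
  w2 <- q2[1]; v2 <- q2[2:4]
  w <- w1 * w2 - sum(v1 * v2)
  v <- w1 * v2 + w2 * v1 + c(v1[2] * v2[3] - v1[3] * v2[2],
                             v1[3] * v2[1] - v1[1] * v2[3],
                             v1[1] * v2[2] - v1[2] * v2[1])
  quaternion(w, v[1], v[2], v[3], normalize = TRUE)
}

#' Rotation matrix of a quaternion
#'
#' @param q a `pt_quat`.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Rotate row vectors by a quaternion
#'
#' @param q a `pt_quat`.
#' @param v an n x 3 matrix (or length-3 vector) of row vectors.
#' @return Rotated matrix of the same shape.
#' @export
quat_rotate <- function(q, v) {
  if (is.null(dim(v))) v <- matrix(v, 1, 3)
  v %*% t(quat_to_matrix(q))
}

#' Rigid-body pose
#'
#' @param position 3-vector, nm.
#' @param orientation a `pt_quat` (identity by default).
#' @return Object of class `pt_pose`.
#' @export
pose <- function(position = c(0, 0, 0), orientation = quaternion()) {
  stopifnot(length(position) == 3, inherits(orientation, "pt_quat"))
  structure(list(position = as.numeric(position), orientation = orientation),
            class = "pt_pose")
}

#' @export
print.pt_pose <- function(x, ...) {
  cat(sprintf("<pose> at (%.3f, %.3f, %.3f), q = (%.4f, %.4f, %.4f, %.4f)\n",
              x$position[1], x$position[2], x$position[3],
              x$orientation[1], x$orientation[2], x$orientation[3],
              x$orientation[4]))
  invisible(x)
}
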