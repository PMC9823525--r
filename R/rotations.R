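#' Axis-angle rotation matrix
#'
#' Builds the 3x3 rotation matrix for a right-handed rotation by `theta`
#' about the unit axis `axis` (Rodrigues' formula).
#'
#' @param axis Unit 3-vector. Must have unit norm to within 1e-9; the axis is
#'   never silently normalised.
#' @param theta Rotation angle in radians.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' axis_angle_matrix(c(0, 0, 1), pi / 2)
#' @export
axis_angle_matrix <- function(axis, theta) {
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 3L, is.finite(theta))
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop("axis must be a unit vector (norm within 1e-9 of 1)")
  S <- skew(axis)
  diag(3) + sin(theta) * S + (1 - cos(theta)) * (S %*% S)
}

skew <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

#' Euler angles to rotation matrix
#'
#' Converts a 3-vector of Euler angles to a rotation matrix using the
#' intrinsic, body-fixed X-then-Y-then-Z convention:
#' `R = Rx(o1) %*% Ry(o2) %*% Rz(o3)`. This is the convention used for the
#' constant joint-frame orientations of the skeletal model.
#'
#' @param o Numeric 3-vector of Euler angles in radians.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(o) {
  o <- as.numeric(o)
  stopifnot(length(o) == 3L, all(is.finite(o)))
  axis_angle_matrix(c(1, 0, 0), o[1]) %*%
    axis_angle_matrix(c(0, 1, 0), o[2]) %*%
    axis_angle_matrix(c(0, 0, 1), o[3])
}

#' Scale a joint-frame translation by body-scale ratios
#'
#' Applies the elementwise scale update `T_hat = T * (beta_hat / beta)`,
#' mapping a default-model translation to the subject's dimensions.
#'
#' @param trans Numeric 3-vector, metres (default-model frame).
#' @param beta_hat Positive 3-vector of subject scale factors.
#' @param beta Positive 3-vector of default scale factors (all ones for the
#'   default model).
#' @return The scaled 3-vector.
#' @export
scale_translation <- function(trans, beta_hat, beta = c(1, 1, 1)) {
  trans <- as.numeric(trans); beta_hat <- as.numeric(beta_hat)
  beta <- as.numeric(beta)
  stopifnot(length(trans) == 3L, length(beta_hat) == 3L, length(beta) == 3L)
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop("default scales beta must be positive and finite")
  trans * (beta_hat / beta)
}

#' Homogeneous rigid transform
#'
#' Assembles a 4x4 homogeneous matrix from a rotation block and a
#' translation column.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric 3-vector.
#' @return A 4x4 rigid transform.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  out <- diag(4)
  out[1:3, 1:3] <- rotation
  out[1:3, 4] <- translation
  out
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Nearest rotation matrix
#'
#' Projects an arbitrary (non-singular) 3x3 matrix onto the closest rotation
#' matrix in the Frobenius norm via the SVD polar factor, with the sign of
#' the smallest singular vector flipped if needed to enforce determinant +1.
#' Useful when a regressor emits an unconstrained 9-vector as a rotation.
#'
#' @param M A finite 3x3 matrix with non-zero determinant.
#' @return The nearest 3x3 rotation matrix.
#' @export
project_to_rotation <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3L, 3L)), all(is.finite(M)))
  if (abs(det(M)) < .Machine$double.eps)
    stop("matrix is singular; no nearest rotation")
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}
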