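# Orientations are proper 3x3 rotation matrices. The viewing direction of a
# projection is the third row of its matrix (the volume is rotated by t(R)
# and integrated along +z), and the CSV sidecar stores ZYZ Euler angles
# R = Rz(rot) %*% Ry(tilt) %*% Rz(psi) in degrees.

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Convert ZYZ Euler angles (degrees) to a rotation matrix
#'
#' @param rot,tilt,psi Euler angles in degrees, `R = Rz(rot) Ry(tilt) Rz(psi)`.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  d <- pi / 180
  rot_z(rot * d) %*% rot_y(tilt * d) %*% rot_z(psi * d)
}

#' Convert a rotation matrix to ZYZ Euler angles (degrees)
#'
#' Inverse of [euler_to_matrix()] up to angle wrapping; at the gimbal
#' singularity (tilt = 0 or 180) `psi` is fixed to 0.
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  tilt <- acos(max(-1, min(1, R[3, 3])))
  if (sin(tilt) > 1e-8) {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else {
    rot <- atan2(R[2, 1], R[1, 1])
    psi <- 0
    if (R[3, 3] < 0) tilt <- pi
  }
  c(rot, tilt, psi) * 180 / pi
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Sample rotations uniformly over SO(3)
#'
#' Draws Haar-distributed rotations via normalised Gaussian quaternions, the
#' standard construction for uniform orientations on the rotation group.
#'
#' @param n number of rotations.
#' @param seed integer seed; the same seed reproduces the same list.
#' @return List of `n` proper 3x3 rotation matrices.
#' @export
#' @examples
#' R <- sample_orientations_uniform(3, seed = 7)[[1]]
#' crossprod(R)  # identity
sample_orientations_uniform <- function(n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    q <- matrix(rnorm(4 * n), ncol = 4)
    q <- q / sqrt(rowSums(q^2))
    lapply(seq_len(n), function(i) quat_to_matrix(q[i, ]))
  })
}

is_rotation_matrix <- function(R, tol = 1e-10) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}
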