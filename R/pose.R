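#' 6-DOF rigid pose
#'
#' Translations in mm, rotations in degrees. Rotations are intrinsic z-y-x
#' Euler angles (rotate about the body z axis, then the new y, then the new
#' x), applied about a rotation centre that defaults to the surface centroid
#' at the time the pose is applied; centroid-centred rotations keep rotation
#' and translation parameters decorrelated during optimisation.
#'
#' @param tx,ty,tz translations, mm.
#' @param rx,ry,rz rotations, degrees.
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  if (!all(is.finite(p))) stop("non-finite pose components")
  structure(as.list(p), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("rigid_pose: t = (%.4g, %.4g, %.4g) mm, r = (%.4g, %.4g, %.4g) deg\n",
              x$tx, x$ty, x$tz, x$rx, x$ry, x$rz))
  invisible(x)
}

#' @rdname rigid_pose
#' @param x numeric length-6 vector (tx, ty, tz, rx, ry, rz).
#' @export
pose_from_vector <- function(x) {
  rigid_pose(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' @rdname rigid_pose
#' @param pose a `rigid_pose`.
#' @export
pose_to_vector <- function(pose) {
  c(pose$tx, pose$ty, pose$tz, pose$rx, pose$ry, pose$rz)
}

# 3x3 rotation matrix for intrinsic z-y-x Euler angles in degrees
rotation_matrix <- function(rx, ry, rz) {
  ax <- rx * pi / 180; ay <- ry * pi / 180; az <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of a pose
#'
#' The matrix maps a point p to `R (p - center) + center + t`.
#'
#' @param pose a [rigid_pose()].
#' @param center 3-vector rotation centre (mm).
#' @export
pose_to_matrix <- function(pose, center = c(0, 0, 0)) {
  R <- rotation_matrix(pose$rx, pose$ry, pose$rz)
  t_full <- center + c(pose$tx, pose$ty, pose$tz) - R %*% center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t_full
  M
}

# Euler z-y-x extraction from a rotation matrix (degrees)
matrix_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(sy) < 1 - 1e-12) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: fold everything into rx
    rx <- atan2(-R[1, 2], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Pose from a homogeneous 4x4 matrix
#' @param M 4x4 homogeneous rigid transform.
#' @param center rotation centre the pose should be expressed about.
#' @export
matrix_to_pose <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  e <- matrix_to_euler(R)
  t_net <- M[1:3, 4] - center + R %*% center
  rigid_pose(t_net[1], t_net[2], t_net[3], e[1], e[2], e[3])
}

#' Compose two poses (apply `p2` first, then `p1`)
#' @param p1,p2 [rigid_pose()] objects.
#' @param center common rotation centre.
#' @export
pose_compose <- function(p1, p2, center = c(0, 0, 0)) {
  matrix_to_pose(pose_to_matrix(p1, center) %*% pose_to_matrix(p2, center),
                 center)
}

#' Inverse pose
#' @param pose a [rigid_pose()].
#' @param center rotation centre.
#' @export
pose_inverse <- function(pose, center = c(0, 0, 0)) {
  matrix_to_pose(solve(pose_to_matrix(pose, center)), center)
}

#' Apply a rigid pose to a surface
#'
#' Vertices are rotated about `center` (default: the surface centroid at call
#' time) and then translated. Identity poses return the input vertices
#' bit-identically; areas are preserved to rounding error.
#'
#' @param surface a [triangle_surface()].
#' @param pose a [rigid_pose()].
#' @param center rotation centre, mm; default the current vertex centroid.
#' @export
apply_pose <- function(surface, pose, center = surface_centroid(surface)) {
  p <- pose_to_vector(pose)
  if (!all(is.finite(p))) stop("non-finite pose components")
  if (all(p == 0)) return(surface)
  R <- rotation_matrix(pose$rx, pose$ry, pose$rz)
  v <- surface$vertices
  vt <- sweep(v, 2, center) %*% t(R)
  vt <- sweep(vt, 2, center + c(pose$tx, pose$ty, pose$tz), `+`)
  out <- surface
  out$vertices <- vt
  attr(out, "edge_table") <- attr(surface, "edge_table")
  out
}
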