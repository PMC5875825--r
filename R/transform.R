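#' 6-DOF rigid-body transform
#'
#' A rigid motion parameterised the way planning-system registration reports
#' are: three translations (mm) and three rotations (degrees) applied about a
#' stated center point. Axes follow DICOM LPS: roll rotates about the
#' superior-inferior axis (z), pitch about the left-right axis (x), yaw about
#' the anterior-posterior axis (y). The rotation matrix is the fixed-axis
#' composition `R = R_yaw %*% R_pitch %*% R_roll`, and the transform maps a
#' point `p` to `R %*% (p - center) + center + t`.
#'
#' Reported translation components depend on the rotation center whenever the
#' rotation is non-trivial; every transform therefore carries its center
#' explicitly and operations refuse to mix centers silently.
#'
#' @param tx,ty,tz translations in mm
#' @param roll,pitch,yaw rotations in degrees (see description for axes)
#' @param center numeric length-3 world point (mm) the rotations act about
#' @return a `rigid_transform` object
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0,
                            roll = 0, pitch = 0, yaw = 0,
                            center = c(0, 0, 0)) {
  p <- unname(c(tx, ty, tz, roll, pitch, yaw))
  if (length(p) != 6L || any(!is.finite(p)))
    stop("transform parameters must be six finite scalars")
  center <- unname(as.numeric(center))
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be 3 finite values (mm)")
  structure(list(tx = p[1], ty = p[2], tz = p[3],
                 roll = p[4], pitch = p[5], yaw = p[6],
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> t = (%.4g, %.4g, %.4g) mm, roll/pitch/yaw = (%.4g, %.4g, %.4g) deg, center (%s) mm\n",
    x$tx, x$ty, x$tz, x$roll, x$pitch, x$yaw,
    paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix of a rigid transform
#' @param T a `rigid_transform`
#' @return 3x3 orthonormal matrix
#' @export
rotation_matrix <- function(T) {
  d <- pi / 180
  rot_y(T$yaw * d) %*% rot_x(T$pitch * d) %*% rot_z(T$roll * d)
}

#' Recover roll/pitch/yaw (degrees) from a rotation matrix
#'
#' Inverse of [rotation_matrix()] for `|pitch| < 90` degrees (no gimbal
#' ambiguity in the tested range; head-scan residual rotations are a few
#' degrees at most).
#' @param R 3x3 rotation matrix
#' @return named numeric: roll, pitch, yaw in degrees
#' @export
angles_from_matrix <- function(R) {
  pitch <- asin(max(-1, min(1, -R[2, 3])))
  roll <- atan2(R[2, 1], R[2, 2])
  yaw <- atan2(R[1, 3], R[3, 3])
  c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
}

#' Apply a rigid transform to world points
#' @param T a `rigid_transform`
#' @param pts n x 3 matrix (or length-3 vector) of world points (mm)
#' @return n x 3 matrix of mapped points
#' @export
transform_points <- function(T, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  R <- rotation_matrix(T)
  t_eff <- c(T$tx, T$ty, T$tz) + T$center - as.numeric(R %*% T$center)
  out <- pts %*% t(R)
  out[, 1] <- out[, 1] + t_eff[1]
  out[, 2] <- out[, 2] + t_eff[2]
  out[, 3] <- out[, 3] + t_eff[3]
  out
}

# 3x4 matrix [R | t_eff] such that p' = R p + t_eff (world -> world)
transform_affine <- function(T) {
  R <- rotation_matrix(T)
  t_eff <- c(T$tx, T$ty, T$tz) + T$center - as.numeric(R %*% T$center)
  cbind(R, t_eff)
}

# rebuild a rigid_transform from R, effective translation, and desired center
transform_from_affine <- function(R, t_eff, center) {
  ang <- angles_from_matrix(R)
  t <- t_eff - center + as.numeric(R %*% center)
  rigid_transform(t[1], t[2], t[3], ang["roll"], ang["pitch"], ang["yaw"],
                  center = center)
}

#' Change the reported rotation center of a transform
#'
#' Returns a transform describing the *same* point mapping with its
#' translation components re-expressed about a new center. Translation
#' components are center-dependent whenever rotations are non-zero.
#' @param T a `rigid_transform`
#' @param center new center (mm)
#' @export
recenter_transform <- function(T, center) {
  A <- transform_affine(T)
  transform_from_affine(A[, 1:3], A[, 4], as.numeric(center))
}

same_center <- function(A, B, tol = 1e-9) all(abs(A$center - B$center) <= tol)

#' Compose two rigid transforms
#'
#' `compose_transform(A, B)` maps a point `p` to `A(B(p))`. Both transforms
#' must carry the same rotation center (use [recenter_transform()] first if
#' they do not); the result is decomposed in that shared convention.
#' @param A,B `rigid_transform` objects with identical centers
#' @export
compose_transform <- function(A, B) {
  if (!same_center(A, B))
    stop("transforms have different rotation centers; recenter_transform() one of them first")
  Aa <- transform_affine(A)
  Bb <- transform_affine(B)
  R <- Aa[, 1:3] %*% Bb[, 1:3]
  t_eff <- as.numeric(Aa[, 1:3] %*% Bb[, 4]) + Aa[, 4]
  transform_from_affine(R, t_eff, A$center)
}

#' Invert a rigid transform
#'
#' Returns the transform mapping `T(p)` back to `p`, reported about the same
#' center.
#' @param T a `rigid_transform`
#' @export
invert_transform <- function(T) {
  A <- transform_affine(T)
  Rinv <- t(A[, 1:3])
  t_eff <- -as.numeric(Rinv %*% A[, 4])
  transform_from_affine(Rinv, t_eff, T$center)
}

#' Is a transform the identity (within tolerance)?
#' @param T a `rigid_transform`
#' @param tol_mm,tol_deg tolerances on translations (mm) and rotations (deg)
#' @export
is_identity_transform <- function(T, tol_mm = 1e-9, tol_deg = 1e-9) {
  all(abs(c(T$tx, T$ty, T$tz)) <= tol_mm) &&
    all(abs(c(T$roll, T$pitch, T$yaw)) <= tol_deg)
}

transform_params <- function(T) {
  c(tx = T$tx, ty = T$ty, tz = T$tz,
    roll = T$roll, pitch = T$pitch, yaw = T$yaw)
}
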