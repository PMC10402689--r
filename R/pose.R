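#' Rigid camera poses
#'
#' A rigid pose is a 4x4 homogeneous transform mapping model-space points
#' (mm) to camera-space points: `x_cam = T %*% x_model`. The camera looks
#' down +z, image u runs right and v runs down (right-handed convention,
#' used consistently across the package).
#'
#' @param matrix 4x4 numeric matrix with an orthonormal rotation block
#'   (det +1) and last row (0, 0, 0, 1).
#' @return An object of class `rigid_pose` (the validated matrix).
#' @examples
#' p <- pose_from_euler(10, 0, 0, t = c(1, 2, 3))
#' pose_compose(p, pose_invert(p))  # identity
#' @export
rigid_pose <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(is.numeric(m), all(dim(m) == c(4L, 4L)), all(is.finite(m)))
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    stop("rotation block is not orthonormal (tolerance 1e-9)")
  }
  if (abs(det(R) - 1) > 1e-9) stop("rotation block must have determinant +1")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12) stop("last row must be (0,0,0,1)")
  structure(m, class = "rigid_pose")
}

#' @rdname rigid_pose
#' @export
pose_identity <- function() rigid_pose(diag(4))

#' @param a,b,p Rigid poses.
#' @rdname rigid_pose
#' @export
pose_compose <- function(a, b) {
  m <- unclass(a) %*% unclass(b)
  # re-orthonormalize drift from long chains before validating
  rigid_pose(reproject_rigid(m))
}

#' @rdname rigid_pose
#' @export
pose_invert <- function(p) {
  m <- unclass(p)
  R <- t(m[1:3, 1:3])
  out <- diag(4)
  out[1:3, 1:3] <- R
  out[1:3, 4] <- -R %*% m[1:3, 4]
  rigid_pose(out)
}

# nearest rotation via SVD; keeps compose() numerically closed under the
# 1e-9 orthogonality invariant.
reproject_rigid <- function(m) {
  s <- svd(m[1:3, 1:3])
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  m[1:3, 1:3] <- R
  m[4, ] <- c(0, 0, 0, 1)
  m
}

rot_axis <- function(axis, deg) {
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  R <- diag(3)
  if (axis == "x") R <- rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_))
  if (axis == "y") R <- rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_))
  if (axis == "z") R <- rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1))
  R
}

#' Build a pose from XYZ Euler angles and a translation
#'
#' Angles are in degrees, intrinsic XYZ order (`R = Rx %*% Ry %*% Rz`),
#' translation in mm. This parameterization is also the 6-vector encoding
#' used by the pose search: `(rx, ry, rz, tx, ty, tz)`.
#'
#' @param rx,ry,rz Euler angles in degrees.
#' @param t Length-3 translation (mm).
#' @return A `rigid_pose`.
#' @export
pose_from_euler <- function(rx, ry, rz, t = c(0, 0, 0)) {
  R <- rot_axis("x", rx) %*% rot_axis("y", ry) %*% rot_axis("z", rz)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  rigid_pose(m)
}

#' @param v Numeric 6-vector `(rx, ry, rz, tx, ty, tz)` in degrees / mm.
#' @rdname pose_from_euler
#' @export
pose_decode <- function(v) {
  stopifnot(length(v) == 6)
  r <- wrap_angle(v[1:3])
  pose_from_euler(r[1], r[2], r[3], t = v[4:6])
}

#' @rdname pose_from_euler
#' @export
pose_encode <- function(p) {
  m <- unclass(p)
  R <- m[1:3, 1:3]
  # R = Rx(rx) Ry(ry) Rz(rz): R[1,3] = sin(ry)
  ry <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  } else {
    # gimbal lock: fold everything into rx
    rx <- atan2(R[3, 2], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi -> ang
  c(ang, m[1:3, 4])
}

wrap_angle <- function(deg) ((deg + 180) %% 360) - 180

#' @rdname rigid_pose
#' @export
pose_translation <- function(p) unclass(p)[1:3, 4]

#' @rdname rigid_pose
#' @export
pose_rotation <- function(p) unclass(p)[1:3, 1:3]

#' Apply a pose to model-space points
#'
#' @param p A `rigid_pose`.
#' @param pts n x 3 matrix of model-space points (mm).
#' @return n x 3 matrix of camera-space points.
#' @export
pose_apply <- function(p, pts) {
  pts <- rbind3(pts)
  m <- unclass(p)
  sweep(pts %*% t(m[1:3, 1:3]), 2, -m[1:3, 4])
}

rbind3 <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  stopifnot(ncol(pts) == 3)
  pts
}

#' Read and write poses as JSON
#'
#' The on-disk format is a JSON object with key `"matrix"` holding the 4x4
#' transform as a row-major list of 16 numbers, units mm.
#'
#' @param path File path.
#' @param p A `rigid_pose`.
#' @export
read_pose <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_pose(matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE))
}

#' @rdname read_pose
#' @export
write_pose <- function(p, path) {
  jsonlite::write_json(
    list(matrix = as.numeric(t(unclass(p))), units = "mm"),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("<rigid_pose> Euler XYZ (deg) / t (mm):",
      paste(sprintf("%.3f", pose_encode(x)), collapse = " "), "\n")
  print(round(unclass(x), 6))
  invisible(x)
}
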