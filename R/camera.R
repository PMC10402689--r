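#' Pinhole camera intrinsics
#'
#' An ideal (distortion-free) pinhole model. Pixel coordinates follow the
#' image convention: origin at the top-left corner, u right, v down; a
#' camera-space point (x, y, z) with z > 0 projects to
#' `u = fx * x / z + cx`, `v = fy * y / z + cy`.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels (inside the image).
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy = fx, cx = width / 2, cy = height / 2,
                              width, height) {
  stopifnot(fx > 0, fy > 0, cx >= 0, cx < width, cy >= 0, cy < height,
            width >= 1, height >= 1)
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy,
         width = as.integer(width), height = as.integer(height)),
    class = "camera_intrinsics"
  )
}

#' Horizontal/vertical field of view of an intrinsics object, degrees
#' @param intr A `camera_intrinsics`.
#' @export
camera_fov <- function(intr) {
  c(h = 2 * atan2(intr$width / 2, intr$fx),
    v = 2 * atan2(intr$height / 2, intr$fy)) * 180 / pi
}

#' Project model-space points to pixel coordinates
#'
#' Points behind the camera (z <= 0) are flagged `projectable = FALSE`
#' (their u, v are NA); points projecting outside the image rectangle are
#' flagged `in_frame = FALSE`. No exceptions are thrown for either case.
#'
#' @param points n x 3 matrix of model-space points (mm).
#' @param pose A `rigid_pose` (model -> camera).
#' @param intr A `camera_intrinsics`.
#' @return A tibble with columns `u`, `v`, `z` (camera depth, mm),
#'   `projectable`, `in_frame`.
#' @export
project_points <- function(points, pose, intr) {
  p <- project_raw(points, pose, intr)
  tibble::tibble(u = ifelse(p$ok, p$u, NA_real_),
                 v = ifelse(p$ok, p$v, NA_real_),
                 z = p$z, projectable = p$ok, in_frame = p$in_frame)
}

# tibble-free projection used on optimizer hot paths
project_raw <- function(points, pose, intr) {
  pc <- pose_apply(pose, points)
  z <- pc[, 3]
  ok <- is.finite(z) & z > 0
  u <- intr$fx * pc[, 1] / z + intr$cx
  v <- intr$fy * pc[, 2] / z + intr$cy
  in_frame <- ok & u >= 0 & u < intr$width & v >= 0 & v < intr$height
  in_frame[is.na(in_frame)] <- FALSE
  list(u = u, v = v, z = z, ok = ok, in_frame = in_frame)
}
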