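#' Parameters for salient structural point extraction
#'
#' @param theta_T Perpendicularity threshold in degrees (0, 90]: a point is
#'   kept when the angle between its surface normal and the viewing ray is
#'   at least `theta_T`. Close to 90 degrees selects thin contours.
#' @param N_s Valid-seed-count threshold: a candidate is salient when the
#'   number of unoccluded seed points on its tangent-plane region is
#'   strictly greater than `N_s`.
#' @param seed_spacing Grid interval (mm) for seeds on the tangent plane.
#' @export
salient_params <- function(theta_T = 80, N_s = 5, seed_spacing = 1.5) {
  stopifnot(theta_T > 0, theta_T <= 90, N_s >= 1, seed_spacing > 0)
  structure(list(theta_T = theta_T, N_s = as.integer(N_s),
                 seed_spacing = seed_spacing),
            class = "salient_params")
}

#' Salient point sets
#'
#' 3D surface points with unit normals and their source vertex ids.
#'
#' @param points k x 3 matrix (mm).
#' @param normals k x 3 matrix of unit normals.
#' @param source_vertex_ids Integer vector of originating mesh vertices.
#' @export
salient_point_set <- function(points, normals, source_vertex_ids = integer(0)) {
  points <- rbind3(points); normals <- rbind3(normals)
  stopifnot(nrow(points) == nrow(normals))
  if (nrow(normals) > 0) {
    stopifnot(max(abs(sqrt(rowSums(normals^2)) - 1)) < 1e-6)
  }
  structure(list(points = points, normals = normals,
                 source_vertex_ids = as.integer(source_vertex_ids)),
            class = "salient_point_set")
}

#' @export
print.salient_point_set <- function(x, ...) {
  cat(sprintf("<salient_point_set> %d points\n", nrow(x$points)))
  invisible(x)
}

#' Intersection of a tangent plane with the pelvic search volume
#'
#' Returns the ellipse in which the plane through `p` with normal `normal`
#' cuts the ellipsoid `vp`, or `NULL` when the plane misses it. The ellipse
#' is parameterized by its 3D center and two orthogonal in-plane axis
#' vectors scaled to the semi-axis lengths.
#'
#' @param p Point on the plane (length 3, mm).
#' @param normal Unit plane normal.
#' @param vp An `ellipsoid`.
#' @return `NULL`, or a list with `center` (3-vector), `axes` (2 x 3 matrix
#'   of semi-axis vectors, mm).
#' @export
tangent_plane_region <- function(p, normal, vp) {
  stopifnot(abs(sqrt(sum(normal^2)) - 1) < 1e-6)
  # map to the metric in which vp is the unit ball: y = (x - c) / s
  s <- vp$semi_axes
  p2 <- (p - vp$center) / s
  n2 <- normal * s           # plane normal transforms covariantly
  n2l <- sqrt(sum(n2^2))
  n2 <- n2 / n2l
  dist <- sum(p2 * n2)       # signed distance of the mapped plane from 0
  if (abs(dist) > 1) return(NULL)
  r <- sqrt(max(0, 1 - dist^2))  # disk radius in the mapped space
  c2 <- dist * n2
  ref <- if (abs(n2[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u2 <- cross3(n2, ref); u2 <- u2 / sqrt(sum(u2^2))
  v2 <- cross3(n2, u2)
  # map the disk {c2 + r(cos t u2 + sin t v2)} back: x = c + s * y
  center <- vp$center + s * c2
  A <- rbind(s * u2 * r, s * v2 * r)  # image of the disk's axes (an ellipse)
  # principal axes of that ellipse via 2x2 eigen decomposition of A A^T
  G <- A %*% t(A)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  axes <- rbind(
    sqrt(max(eg$values[1], 0)) * normalize_in_plane(eg$vectors[, 1], A),
    sqrt(max(eg$values[2], 0)) * normalize_in_plane(eg$vectors[, 2], A)
  )
  list(center = center, axes = axes)
}

normalize_in_plane <- function(coef, A) {
  v <- coef[1] * A[1, ] + coef[2] * A[2, ]
  l <- sqrt(sum(v^2))
  if (l < 1e-12) return(A[1, ] / max(sqrt(sum(A[1, ]^2)), 1e-12))
  v / l
}

region_seed_points <- function(region, spacing) {
  a <- sqrt(sum(region$axes[1, ]^2))
  b <- sqrt(sum(region$axes[2, ]^2))
  if (a < 1e-9 || b < 1e-9) return(matrix(region$center, 1))
  u <- region$axes[1, ] / a
  v <- region$axes[2, ] / b
  xs <- unique(c(-rev(seq(0, a, by = spacing)), seq(0, a, by = spacing)))
  ys <- unique(c(-rev(seq(0, b, by = spacing)), seq(0, b, by = spacing)))
  if (length(xs) <= 1 && length(ys) <= 1) return(matrix(region$center, 1))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x / a)^2 + (g$y / b)^2 <= 1
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) return(matrix(region$center, 1))
  t(apply(g, 1, function(r) region$center + r[1] * u + r[2] * v))
}

#' Seed-visibility (collision) filter for one candidate point
#'
#' Lays a square grid of seed points (pitch `seed_spacing`) over the
#' tangent-plane region and counts seeds with an unobstructed line of
#' sight to `p` (mesh triangles are the obstacles). The candidate is
#' salient when strictly more than `N_s` seeds are valid. Degenerate
#' regions (smaller than one grid cell) fall back to the region center as
#' a single seed.
#'
#' @param p Candidate surface point (length 3).
#' @param region Output of [tangent_plane_region()].
#' @param mesh A `tri_mesh`.
#' @param params A `salient_params`.
#' @return List with `is_salient` and `n_valid_seeds`.
#' @export
collision_filter <- function(p, region, mesh, params = salient_params()) {
  stopifnot(!is.null(region))
  seeds <- region_seed_points(region, params$seed_spacing)
  occ <- segment_occluded(seeds, matrix(p, nrow(seeds), 3, byrow = TRUE), mesh)
  n_valid <- sum(!occ)
  list(is_salient = n_valid > params$N_s, n_valid_seeds = n_valid)
}

#' Extract the salient structural point set of a cavity
#'
#' Iterates mesh vertices; a vertex is salient when (a) its tangent plane
#' intersects the pelvic volume `vp` (so a camera placed in `vp` can view
#' it edge-on: the perpendicularity condition is attainable), and (b) the
#' seed-visibility filter passes (the point is actually observable from
#' enough of that tangent-plane region). On branched cavities the
#' surviving points concentrate on calyx rims and pelvis-calyx junctions.
#'
#' @param mesh A `tri_mesh` with unit vertex normals.
#' @param vp An `ellipsoid` inside the lumen.
#' @param params A `salient_params`.
#' @return A `salient_point_set` (possibly empty, with a warning).
#' @export
extract_salient_points <- function(mesh, vp, params = salient_params()) {
  V <- mesh$vertices
  N <- mesh$normals
  keep <- logical(nrow(V))
  for (i in seq_len(nrow(V))) {
    region <- tangent_plane_region(V[i, ], N[i, ], vp)
    if (is.null(region)) next
    keep[i] <- collision_filter(V[i, ], region, mesh, params)$is_salient
  }
  if (!any(keep)) warning("no salient points found; enlarge vp or relax params")
  salient_point_set(V[keep, , drop = FALSE], N[keep, , drop = FALSE],
                    which(keep))
}

#' Select the per-pose subset of salient points
#'
#' Keeps a point when (a) the angle between its normal and the viewing ray
#' (mapped to `[0, 90]` degrees via the absolute cosine, so surface
#' orientation sign cannot flip the test) is at least `theta_T`; (b) the
#' segment from the optical center to the point is unoccluded; (c) it
#' projects inside the image with positive depth.
#'
#' @param F_set A `salient_point_set`.
#' @param pose A `rigid_pose`.
#' @param intr A `camera_intrinsics`.
#' @param mesh A `tri_mesh` (occlusion geometry).
#' @param theta_T Perpendicularity threshold (degrees).
#' @param check_occlusion Set `FALSE` to skip the (expensive) occlusion
#'   test, e.g. when a visibility cache already applied it.
#' @return A `salient_point_set`.
#' @export
select_for_pose <- function(F_set, pose, intr, mesh,
                            theta_T = salient_params()$theta_T,
                            check_occlusion = TRUE) {
  if (nrow(F_set$points) == 0) return(F_set)
  oc <- camera_center(pose)
  w <- sweep(F_set$points, 2, oc)  # viewing rays
  wlen <- sqrt(rowSums(w^2))
  w <- w / pmax(wlen, 1e-12)
  cosang <- abs(rowSums(w * F_set$normals))
  theta <- acos(pmin(1, pmax(0, cosang))) * 180 / pi
  keep <- theta >= theta_T
  if (any(keep)) {
    prj <- project_raw(F_set$points[keep, , drop = FALSE], pose, intr)
    keep[keep] <- prj$ok & prj$in_frame
  }
  if (check_occlusion && any(keep)) {
    occ <- segment_occluded(matrix(oc, sum(keep), 3, byrow = TRUE),
                            F_set$points[keep, , drop = FALSE], mesh)
    keep[keep] <- !occ
  }
  salient_point_set(F_set$points[keep, , drop = FALSE],
                    F_set$normals[keep, , drop = FALSE],
                    F_set$source_vertex_ids[keep])
}

camera_center <- function(pose) {
  m <- unclass(pose)
  as.numeric(-t(m[1:3, 1:3]) %*% m[1:3, 4])
}

#' Project a selected salient point set to a generated contour
#'
#' @param P A pose-filtered `salient_point_set`.
#' @param pose A `rigid_pose`.
#' @param intr A `camera_intrinsics`.
#' @return A `contour2d` with source `"generated"` and empty gradients.
#' @export
generate_contour <- function(P, pose, intr) {
  if (nrow(P$points) == 0) {
    return(contour2d(matrix(0, 0, 2), source = "generated"))
  }
  prj <- project_raw(P$points, pose, intr)
  ok <- prj$ok & prj$in_frame
  contour2d(cbind(prj$u[ok], prj$v[ok]), source = "generated")
}

#' Export a salient point set as a data frame / CSV
#'
#' @param F_set A `salient_point_set`.
#' @return Tibble with x, y, z, nx, ny, nz, vertex_id.
#' @export
salient_as_tibble <- function(F_set) {
  tibble::tibble(
    x = F_set$points[, 1], y = F_set$points[, 2], z = F_set$points[, 3],
    nx = F_set$normals[, 1], ny = F_set$normals[, 2], nz = F_set$normals[, 3],
    vertex_id = if (length(F_set$source_vertex_ids)) F_set$source_vertex_ids
                else rep(NA_integer_, nrow(F_set$points))
  )
}
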