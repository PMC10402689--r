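#' Ray-triangle intersection
#'
#' Moller-Trumbore test of one ray against one triangle. Returns the
#' smallest hit distance `t` in `(1e-6, max_t]` (the lower guard protects
#' against self-intersection when the origin lies on a surface), or `NA`
#' when the ray misses. Degenerate triangles (area < 1e-12) are skipped
#' and count as misses.
#'
#' @param origin,direction Ray origin and direction (length-3; direction
#'   is normalized internally).
#' @param v0,v1,v2 Triangle vertices (length-3 each, mm).
#' @param max_t Maximum admissible hit distance (mm).
#' @return Hit distance in mm, or `NA_real_`.
#' @export
ray_triangle_intersect <- function(origin, direction, v0, v1, v2, max_t = Inf) {
  d <- direction / sqrt(sum(direction^2))
  t <- ray_triangle_single_cpp(as.numeric(origin), as.numeric(d),
                               as.numeric(v0), as.numeric(v1), as.numeric(v2),
                               if (is.finite(max_t)) max_t else 1e300)
  if (t < 0) NA_real_ else t
}

#' Segment occlusion test against a mesh
#'
#' `TRUE` iff any mesh triangle intersects the open segment (p, q). Hits
#' within `eps_end` (mm) of `q` are ignored, so `q` may lie on the surface
#' itself; the 1e-6 ray guard protects the `p` end.
#'
#' @param p,q Segment endpoints (length-3 vectors, or n x 3 matrices for a
#'   batch; recycled row-wise).
#' @param mesh A `tri_mesh`.
#' @param eps_end Exclusion distance around `q` in mm.
#' @return Logical vector, one per segment.
#' @export
segment_occluded <- function(p, q, mesh, eps_end = 1e-4) {
  p <- rbind3(p); q <- rbind3(q)
  if (nrow(p) == 1 && nrow(q) > 1) p <- p[rep(1, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1 && nrow(p) > 1) q <- q[rep(1, nrow(p)), , drop = FALSE]
  if (nrow(mesh$faces) == 0) return(rep(FALSE, nrow(p)))
  as.logical(segments_occluded_cpp(mesh_accel(mesh), p, q, eps_end))
}

#' Cast rays against a mesh
#'
#' @param origins,directions n x 3 matrices (directions normalized
#'   internally).
#' @param mesh A `tri_mesh`.
#' @param max_t Maximum hit distance (mm).
#' @return A tibble with `t` (Inf on miss) and `face` (0 on miss).
#' @export
cast_rays <- function(origins, directions, mesh, max_t = Inf) {
  origins <- rbind3(origins); directions <- rbind3(directions)
  directions <- directions / sqrt(rowSums(directions^2))
  res <- accel_raycast_cpp(mesh_accel(mesh), origins, directions,
                           if (is.finite(max_t)) max_t else 1e300)
  tibble::tibble(t = res$t, face = res$face)
}

#' Inside/outside test for closed meshes
#'
#' Ray-parity test: a point is inside iff a ray to infinity crosses the
#' surface an odd number of times. Three fixed, incommensurate directions
#' vote to make the test robust to rays grazing shared edges.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh A closed `tri_mesh`.
#' @return Logical vector.
#' @export
points_inside_mesh <- function(points, mesh) {
  points <- rbind3(points)
  dirs <- rbind(
    c(0.5369795, 0.7308782, 0.4211076),
    c(-0.3990159, 0.5466335, 0.7362575),
    c(0.8063, -0.2104, -0.5528)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  acc <- mesh_accel(mesh)
  votes <- vapply(1:3, function(k) {
    dm <- matrix(dirs[k, ], nrow(points), 3, byrow = TRUE)
    count_crossings_cpp(acc, points, dm) %% 2L == 1L
  }, logical(nrow(points)))
  votes <- matrix(votes, nrow = nrow(points))
  rowSums(votes) >= 2
}

#' Unsigned distance from points to the mesh surface
#'
#' Exact point-to-triangle distances (minimum over all faces).
#'
#' @param points n x 3 matrix (mm).
#' @param mesh A `tri_mesh`.
#' @return Numeric vector of distances (mm).
#' @export
distance_to_surface <- function(points, mesh) {
  as.numeric(surface_distance_cpp(mesh_accel(mesh), rbind3(points)))
}
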