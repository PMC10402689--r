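# Shared fixtures, memoized once per test run. All geometry is generated
# in code; nothing is read from disk.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

# closed sphere cavity of radius r with inward normals (analytic null case)
sphere_cavity <- function(r = 10, level = 3) {
  memo(paste0("sphere", r, "_", level), {
    ico <- lumenreg:::icosphere(level)
    mesh_prepare(tri_mesh(ico$V * r, ico$F[, c(1, 3, 2)]))
  })
}

k1_scene <- function() {
  memo("k1_scene", build_scene(scene_spec_k1(), n_poses = 4, seed = 1))
}

k2_scene <- function() {
  memo("k2_scene", build_scene(scene_spec_k2(), n_poses = 4, seed = 1))
}

# the registration protocol used by the recovery studies: reference view =
# the one with the most extractable contour points, all others auxiliary
protocol_context <- function(scene, key) {
  memo(paste0("ctx_", key), {
    counts <- vapply(scene$views, function(v) {
      contour_size(extract_actual_contours(v$image))
    }, integer(1))
    ref <- which.max(counts)
    suppressMessages(registration_context(
      scene, view = ref, aux_view = setdiff(seq_along(scene$views), ref)
    ))
  })
}

random_pose <- function() {
  pose_from_euler(runif(1, -180, 180), runif(1, -89, 89), runif(1, -180, 180),
                  t = runif(3, -20, 20))
}

# independent brute-force oracle for the joint-probability MI costs:
# explicit double loops, no shared code with the package implementation
oracle_mi <- function(W) {
  n <- nrow(W); m <- ncol(W)
  P <- W / sum(W)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (P[i, j] > 0) {
        rs <- sum(P[i, ])
        cs <- sum(P[, j])
        total <- total + P[i, j] * log(P[i, j] / (rs * cs))
      }
    }
  }
  total
}

oracle_position_cost <- function(A, B, length_scale) {
  n <- nrow(A); m <- nrow(B)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      W[i, j] <- exp(-sqrt(sum((A[i, ] - B[j, ])^2)) / length_scale)
    }
  }
  oracle_mi(W)
}

oracle_gradient_cost <- function(mag_a, ori_a, mag_b, ori_b) {
  n <- length(mag_a); m <- length(mag_b)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      mm <- abs(mag_a[i] - mag_b[j])
      dd <- abs(ori_a[i] - ori_b[j])
      oo <- min(dd, pi - dd) / (pi / 2)
      W[i, j] <- exp(-(mm + oo))
    }
  }
  oracle_mi(W)
}

# barycentric-coordinate ray/triangle oracle (plane intersection + inside
# test), independent of the Moller-Trumbore kernel
oracle_ray_triangle <- function(o, d, v0, v1, v2, max_t = Inf) {
  n <- lumenreg:::cross3(v1 - v0, v2 - v0)
  area2 <- sqrt(sum(n^2))
  if (area2 * 0.5 < 1e-12) return(NA_real_)
  denom <- sum(n * d)
  if (abs(denom) < 1e-12) return(NA_real_)
  t <- sum(n * (v0 - o)) / denom
  if (t <= 1e-6 || t > max_t) return(NA_real_)
  p <- o + t * d
  # barycentric via sub-areas with sign
  w0 <- sum(n * lumenreg:::cross3(v1 - p, v2 - p)) / sum(n * n)
  w1 <- sum(n * lumenreg:::cross3(v2 - p, v0 - p)) / sum(n * n)
  w2 <- sum(n * lumenreg:::cross3(v0 - p, v1 - p)) / sum(n * n)
  if (w0 >= -1e-9 && w1 >= -1e-9 && w2 >= -1e-9) t else NA_real_
}

expect_pose_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(unclass(a) - unclass(b))), tol)
}
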