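test_that("tangent-plane / search-volume intersection follows sphere-slice geometry", {
  vp <- ellipsoid(c(0, 0, 0), c(1, 1, 1))
  # plane z = 2 misses the unit ball
  expect_null(tangent_plane_region(c(0, 0, 2), c(0, 0, 1), vp))
  # plane z = 0.5 cuts a disk of radius sqrt(0.75)
  reg <- tangent_plane_region(c(0, 0, 0.5), c(0, 0, 1), vp)
  expect_equal(reg$center, c(0, 0, 0.5), tolerance = 1e-9)
  expect_equal(sort(sqrt(rowSums(reg$axes^2))), rep(sqrt(0.75), 2),
               tolerance = 1e-9)
  # supporting-plane property: tangent planes of an enclosing sphere miss
  # any interior ball
  vp_small <- ellipsoid(c(0, 0, 0), c(5, 5, 5))
  p <- c(10, 0, 0)
  expect_null(tangent_plane_region(p, c(1, 0, 0), vp_small))
  # anisotropic volume: region exists iff the Vp-metric distance is < 1
  vp_e <- ellipsoid(c(0, 0, 0), c(4, 2, 1))
  expect_null(tangent_plane_region(c(0, 0, 1.5), c(0, 0, 1), vp_e))
  expect_false(is.null(tangent_plane_region(c(0, 0, 0.5), c(0, 0, 1), vp_e)))
})

test_that("seed-visibility filter counts unoccluded tangent-plane seeds", {
  vp <- ellipsoid(c(0, 0, 0), c(6, 6, 6))
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(integer(0), 0, 3)), class = "tri_mesh")
  reg <- tangent_plane_region(c(0, 0, 0), c(0, 0, 1), vp)
  params <- salient_params(N_s = 5, seed_spacing = 1.5)
  res <- collision_filter(c(0, 0, 0), reg, empty, params)
  expect_true(res$is_salient)
  expect_gt(res$n_valid_seeds, 5)

  # a wall between the whole region and the point blocks every seed
  wall <- tri_mesh(rbind(c(-50, -50, 5), c(50, -50, 5), c(50, 50, 5), c(-50, 50, 5)),
                   rbind(c(1, 2, 3), c(1, 3, 4)))
  p_behind <- c(0, 0, 10)
  reg2 <- tangent_plane_region(p_behind, c(1, 0, 0), ellipsoid(c(0, 0, 0), c(3, 3, 3)))
  res2 <- collision_filter(p_behind, reg2, wall, params)
  expect_false(res2$is_salient)
  expect_equal(res2$n_valid_seeds, 0)

  # pigeonhole: threshold above the total seed count can never pass
  n_seeds <- nrow(lumenreg:::region_seed_points(reg, 1.5))
  big <- salient_params(N_s = n_seeds + 1, seed_spacing = 1.5)
  expect_false(collision_filter(c(0, 0, 0), reg, empty, big)$is_salient)
})

test_that("a sphere cavity with interior search volume has no salient points", {
  mesh <- sphere_cavity(r = 10)
  vp <- ellipsoid(c(0, 0, 0), c(5, 5, 5))
  expect_warning(F_set <- extract_salient_points(mesh, vp), "no salient")
  expect_equal(nrow(F_set$points), 0)
})

test_that("salient points concentrate on calyx junction rims", {
  scene <- k2_scene()
  F_set <- extract_salient_points(scene$mesh, scene$vp)
  expect_gt(nrow(F_set$points), 20)
  rims <- junction_rims(scene$mesh)
  nn <- apply(lumenreg:::pair_dist(F_set$points, rims), 1, min)
  expect_gte(mean(nn <= 3), 0.8)
  # idempotence: every reported point re-passes its own two tests
  params <- salient_params()
  for (i in seq_len(min(25, nrow(F_set$points)))) {
    reg <- tangent_plane_region(F_set$points[i, ], F_set$normals[i, ], scene$vp)
    expect_false(is.null(reg))
    expect_true(collision_filter(F_set$points[i, ], reg, scene$mesh, params)$is_salient)
  }
})

test_that("per-pose selection applies the perpendicularity rule exactly", {
  intr <- camera_intrinsics(fx = 100, width = 200, height = 200)
  empty_mesh <- structure(list(vertices = matrix(0, 0, 3),
                               faces = matrix(integer(0), 0, 3)),
                          class = "tri_mesh")
  # camera at sphere center: all normals parallel to viewing rays -> empty
  mesh <- sphere_cavity(r = 10)
  Fs <- salient_point_set(mesh$vertices, mesh$normals,
                          seq_len(nrow(mesh$vertices)))
  sel <- select_for_pose(Fs, pose_identity(), intr, mesh, theta_T = 80)
  expect_equal(nrow(sel$points), 0)

  # orthogonal normal is kept at any threshold; normals 87 deg vs 80 deg
  # from the viewing ray split exactly around theta_T = 85
  mk <- function(normal) salient_point_set(matrix(c(0, 0, 10), 1),
                                           matrix(normal, 1), 1L)
  kept <- function(normal, theta_T) {
    nrow(select_for_pose(mk(normal), pose_identity(), intr, empty_mesh,
                         theta_T = theta_T)$points) == 1
  }
  expect_true(kept(c(1, 0, 0), 90))                        # exactly orthogonal
  n87 <- c(sin(87 * pi / 180) * 1, 0, cos(87 * pi / 180))  # 87 deg from ray
  n80 <- c(sin(80 * pi / 180) * 1, 0, cos(80 * pi / 180))
  expect_true(kept(n87 / sqrt(sum(n87^2)), 85))
  expect_false(kept(n80 / sqrt(sum(n80^2)), 85))
  # sign of the normal cannot flip the decision
  expect_true(kept(-n87 / sqrt(sum(n87^2)), 85))
})

test_that("selection is monotone in the perpendicularity threshold", {
  scene <- k2_scene()
  F_set <- extract_salient_points(scene$mesh, scene$vp)
  pose <- scene$gt_poses[[1]]
  sizes <- vapply(c(60, 70, 80, 85, 89), function(th) {
    nrow(select_for_pose(F_set, pose, scene$intrinsics, scene$mesh, th)$points)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("generated contours are projections of the selected points", {
  intr <- camera_intrinsics(fx = 100, width = 200, height = 200)
  empty <- salient_point_set(matrix(0, 0, 3), matrix(0, 0, 3))
  expect_equal(contour_size(generate_contour(empty, pose_identity(), intr)), 0)
  one <- salient_point_set(matrix(c(0, 0, 10), 1), matrix(c(1, 0, 0), 1), 1L)
  g <- generate_contour(one, pose_identity(), intr)
  expect_equal(as.numeric(g$points), c(100, 100))
  expect_identical(g$source, "generated")
  # projection never adds points
  scene <- k2_scene()
  F_set <- extract_salient_points(scene$mesh, scene$vp)
  P <- select_for_pose(F_set, scene$gt_poses[[1]], scene$intrinsics, scene$mesh, 80)
  expect_lte(contour_size(generate_contour(P, scene$gt_poses[[1]], scene$intrinsics)),
             nrow(P$points))
})

test_that("generated contours land on rendered depth edges", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  i <- ctx$view
  gen <- context_generated_contour(ctx, scene$gt_poses[[i]])
  mask <- silhouette_depth_edges(scene$views[[i]]$depth, 3)
  idx <- which(mask, arr.ind = TRUE)
  mask_pts <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)
  nn <- apply(lumenreg:::pair_dist(gen$points, mask_pts), 1, min)
  expect_gte(mean(nn <= 2), 0.7)
})
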