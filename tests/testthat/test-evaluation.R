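test_that("mTRE matches closed forms for translations and rotations", {
  set.seed(71)
  markers <- matrix(runif(30, -30, 30), 10)
  gt <- random_pose()
  expect_equal(as.numeric(mtre(gt, gt, markers)), 0)
  # a pure 1 mm translation moves every marker exactly 1 mm
  off <- pose_compose(pose_from_euler(0, 0, 0, t = c(1, 0, 0)), gt)
  expect_equal(as.numeric(mtre(gt, off, markers)), 1, tolerance = 1e-9)
  # a z-rotation by theta moves each marker along a chord: 2 r sin(theta/2)
  theta <- 25
  rot <- pose_compose(pose_from_euler(0, 0, theta), gt)
  d <- attr(mtre(gt, rot, markers), "per_marker")
  r_axis <- sqrt(rowSums(pose_apply(gt, markers)[, 1:2]^2))
  expect_equal(d, 2 * r_axis * sin(theta / 2 * pi / 180), tolerance = 1e-9)
  expect_error(mtre(gt, gt, matrix(0, 0, 3)), "marker")
})

test_that("orientation and position errors read off pose differences", {
  p <- random_pose()
  expect_equal(orientation_error(p, p), 0)
  expect_equal(position_error(p, p), 0)
  rz <- pose_compose(pose_from_euler(0, 0, 10), pose_from_euler(0, 0, 0))
  expect_equal(orientation_error(pose_identity(), rz), 10, tolerance = 1e-9)
  expect_equal(position_error(pose_identity(), rz), 0)
  tr <- pose_from_euler(0, 0, 0, t = c(3, 4, 0))
  expect_equal(orientation_error(pose_identity(), tr), 0, tolerance = 1e-6)
  expect_equal(position_error(pose_identity(), tr), 5)
})

test_that("mTRE is a symmetric isometry-invariant distance", {
  set.seed(72)
  markers <- matrix(runif(15, -20, 20), 5)
  for (i in 1:20) {
    a <- random_pose(); b <- random_pose(); common <- random_pose()
    m1 <- as.numeric(mtre(a, b, markers))
    expect_equal(m1, as.numeric(mtre(b, a, markers)), tolerance = 1e-9)
    expect_equal(m1, as.numeric(mtre(pose_compose(common, a),
                                     pose_compose(common, b), markers)),
                 tolerance = 1e-8)
  }
  # OE, PE and mTRE vanish together only for equal poses
  a <- random_pose()
  near <- pose_decode(pose_encode(a) + c(1e-12, 0, 0, 0, 0, 0))
  expect_lt(orientation_error(a, near), 1e-9)
  b <- random_pose()
  expect_gt(orientation_error(a, b) + position_error(a, b) +
              as.numeric(mtre(a, b, markers)), 1e-3)
})

test_that("contour agreement is the mean nearest-mask distance", {
  mask <- matrix(FALSE, 50, 50)
  mask[, 25] <- TRUE  # vertical line at u = 24.5
  pts <- contour2d(rbind(c(24.5, 9.5), c(31.5, 39.5)))
  expect_equal(contour_agreement(pts, mask), mean(c(0, 7)), tolerance = 1e-9)
  on_mask <- contour2d(matrix(c(24.5, 3.5), 1))
  expect_equal(contour_agreement(on_mask, mask), 0, tolerance = 1e-9)
  expect_error(contour_agreement(contour2d(matrix(0, 0, 2)), mask), "empty")
  expect_error(contour_agreement(pts, matrix(FALSE, 5, 5)), "mask")
})

test_that("trial suites with no perturbation recover the exact pose", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  cfg <- de_config(population_size = 8, max_iterations_coarse = 2,
                   max_iterations_fine = 2, rng_seed = 1)
  tm <- trial_suite(scene, n_trials = 2, range_half = c(1e-13, 1e-13),
                    cfg = cfg, seed = 0, context = ctx)
  expect_equal(nrow(tm), 2)
  expect_true(all(tm$final_mtre < 1e-6))
  expect_true(all(tm$initial_mtre < 1e-6))
  s <- attr(tm, "summary")
  expect_equal(s$mean[s$metric == "final_mtre"], mean(tm$final_mtre),
               ignore_attr = TRUE)
  # reproducible per seed
  tm2 <- trial_suite(scene, n_trials = 2, range_half = c(1e-13, 1e-13),
                     cfg = cfg, seed = 0, context = ctx)
  expect_identical(tm$final_mtre, tm2$final_mtre)
})

test_that("registration evaluation reports one row per stage", {
  scene <- k2_scene()
  gt <- scene$gt_poses[[1]]
  fake <- structure(list(pose_coarse = gt, pose_fine = gt),
                    class = "registration_result")
  T0 <- perturb_pose(gt, search_range(gt, 10, 5), seed = 3)
  ev <- evaluate_registration(fake, gt, scene$markers, T0 = T0)
  expect_identical(ev$stage, c("initial", "coarse", "fine"))
  expect_equal(ev$mtre[2:3], c(0, 0), ignore_attr = TRUE)
  expect_gt(ev$mtre[1], 0)
})
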