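test_that("position cost matches the brute-force double-loop oracle exactly", {
  set.seed(61)
  for (i in 1:60) {
    n <- sample(2:50, 1); m <- sample(2:50, 1)
    A <- matrix(runif(2 * n, 0, 200), n)
    B <- matrix(runif(2 * m, 0, 200), m)
    got <- position_cost(contour2d(A), contour2d(B), length_scale = 20)
    expect_lt(abs(got - oracle_position_cost(A, B, 20)), 1e-12)
  }
})

test_that("gradient cost matches the brute-force double-loop oracle exactly", {
  set.seed(62)
  for (i in 1:40) {
    n <- sample(2:40, 1); m <- sample(2:40, 1)
    ca <- contour2d(matrix(runif(2 * n), n), grad_mag = runif(n),
                    grad_ori = runif(n, 0, pi))
    cb <- contour2d(matrix(runif(2 * m), m), grad_mag = runif(m),
                    grad_ori = runif(m, 0, pi))
    got <- gradient_cost(ca, cb)
    expect_lt(abs(got - oracle_gradient_cost(ca$grad_mag, ca$grad_ori,
                                             cb$grad_mag, cb$grad_ori)), 1e-12)
  }
})

test_that("analytic cost cases hold", {
  # coincident single pair: degenerate joint, C_p = 0
  a <- contour2d(matrix(c(5, 5), 1))
  expect_equal(position_cost(a, a, 20), 0, tolerance = 1e-12)
  # single-row joint always factorizes
  b <- contour2d(rbind(c(0, 0), c(30, 40)))
  expect_equal(position_cost(a, b, 20), 0, tolerance = 1e-12)
  # two matched far-separated pairs approach ln 2
  pts <- rbind(c(0, 0), c(200, 0))  # 10 length-scales apart
  expect_equal(position_cost(contour2d(pts), contour2d(pts), 20), log(2),
               tolerance = 1e-3)
  # uniform gradient joint factorizes to zero
  u <- contour2d(matrix(runif(8), 4), grad_mag = rep(0.5, 4), grad_ori = rep(1, 4))
  expect_equal(gradient_cost(u, u), 0, tolerance = 1e-12)
  # 2x2 diagonal gradient structure: symmetric joint with off-diagonal
  # weight q = exp(-(1 + 1)); closed-form MI = 2a ln 4a + 2b ln 4b
  ga <- contour2d(matrix(0, 2, 2), grad_mag = c(0, 1), grad_ori = c(0, pi / 2))
  q <- exp(-2)
  pd <- 1 / (2 * (1 + q)); po <- q / (2 * (1 + q))
  expect_equal(gradient_cost(ga, ga), 2 * pd * log(4 * pd) + 2 * po * log(4 * po),
               tolerance = 1e-12)
  # and it approaches ln 2 as the mismatch grows (here via position cost
  # with arbitrarily large distances, since m + o is bounded by 2)
  # single gradient pair is degenerate
  s1 <- contour2d(matrix(0, 1, 2), grad_mag = 0.3, grad_ori = 0.1)
  expect_equal(gradient_cost(s1, s1), 0, tolerance = 1e-12)
  # empty sets are an error, not a silent zero
  expect_error(position_cost(contour2d(matrix(0, 0, 2)), b), "no contour")
  expect_error(gradient_cost(a, b), "gradient attributes")
})

test_that("the MI form is bounded, symmetric, and rigid-invariant", {
  set.seed(63)
  for (i in 1:100) {
    n <- sample(2:30, 1); m <- sample(2:30, 1)
    A <- matrix(runif(2 * n, 0, 100), n)
    B <- matrix(runif(2 * m, 0, 100), m)
    cp <- position_cost(contour2d(A), contour2d(B), 10)
    expect_gte(cp, 0)
    expect_lte(cp, log(min(n, m)) + 1e-9)
    # transpose symmetry
    expect_lt(abs(cp - position_cost(contour2d(B), contour2d(A), 10)), 1e-12)
    # common rigid motion of both sets preserves distances hence the cost
    th <- runif(1, 0, 2 * pi); t <- runif(2, -50, 50)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    cp2 <- position_cost(contour2d(sweep(A %*% t(R), 2, -t)),
                         contour2d(sweep(B %*% t(R), 2, -t)), 10)
    expect_lt(abs(cp - cp2), 1e-9)
  }
})

test_that("auxiliary pose composes the inter-frame motion with the candidate", {
  T0 <- random_pose()
  T0n <- random_pose()
  expect_pose_equal(auxiliary_view_pose(pose_identity(), T0n), T0n)
  # when T0n is the identity motion the auxiliary pose is the candidate
  expect_pose_equal(auxiliary_view_pose(T0, pose_identity()), T0)
  # scene round trip: the stored chain reproduces every ground-truth view pose
  scene <- k2_scene()
  for (n in 2:4) {
    t0n <- pose_compose(scene$relative_transforms[[n]],
                        pose_invert(scene$relative_transforms[[1]]))
    expect_pose_equal(auxiliary_view_pose(scene$gt_poses[[1]], t0n),
                      scene$gt_poses[[n]], 1e-8)
  }
})

test_that("fine cost honours weight degeneracies and the breakdown identity", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  pose <- scene$gt_poses[[ctx$view]]
  w <- cost_weights(0.4, 0.2, 0.4)
  cb <- fine_cost(ctx, pose, w)
  expect_equal(cb$c_fine, 0.4 * cb$c_pos + 0.2 * cb$c_grad + 0.4 * cb$c_pos_aux,
               tolerance = 1e-12)
  w1only <- fine_cost(ctx, pose, cost_weights(1, 0, 0))
  expect_equal(w1only$c_fine, w1only$c_pos, tolerance = 1e-12)
  expect_equal(w1only$c_pos, cb$c_pos, tolerance = 1e-12)
  # an auxiliary view identical to the reference with identity motion
  # reproduces the single-view position cost
  ctx_self <- suppressMessages(
    registration_context(scene, view = ctx$view, aux_view = ctx$view)
  )
  cb_self <- fine_cost(ctx_self, pose, cost_weights(0, 0, 1))
  expect_equal(cb_self$c_pos_aux, cb_self$c_pos, tolerance = 1e-9)
  expect_equal(cb_self$c_fine, cb_self$c_pos, tolerance = 1e-9)
})

test_that("the fine cost peaks at the true pose against far perturbations", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  gt <- scene$gt_poses[[ctx$view]]
  w <- cost_weights(0.4, 0.2, 0.4)
  c_gt <- fine_cost(ctx, gt, w)$c_fine
  x0 <- pose_encode(gt)
  set.seed(64)
  wins <- 0
  for (i in 1:50) {
    repeat {
      d <- runif(6, -1, 1) * c(15, 15, 15, 10, 10, 10)
      if (sqrt(sum(d[1:3]^2)) >= 5 && sqrt(sum(d[4:6]^2)) >= 3) break
    }
    if (c_gt >= fine_cost(ctx, pose_decode(x0 + d), w)$c_fine) wins <- wins + 1
  }
  expect_gte(wins, 45)
})
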