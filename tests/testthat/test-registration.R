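test_that("differential evolution recovers a known quadratic optimum", {
  target <- c(3, -7, 2, 0.5, -1, 4)
  obj <- function(x) -sum((x - target)^2)
  res <- lumenreg:::de_optimize(obj, lo = target - 10, hi = target + 10,
                                n_pop = 30, n_gen = 120, F = 0.7, CR = 0.9,
                                seed = 5, tol = 1e-12, patience = 40)
  expect_lt(max(abs(res$best_x - target)), 1e-2)
  # deterministic per seed
  res2 <- lumenreg:::de_optimize(obj, lo = target - 10, hi = target + 10,
                                 n_pop = 30, n_gen = 120, F = 0.7, CR = 0.9,
                                 seed = 5, tol = 1e-12, patience = 40)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$best_x, res2$best_x)
})

test_that("every DE evaluation respects the box constraints", {
  lo <- c(-2, 0, 5); hi <- c(1, 3, 6)
  seen_out <- FALSE
  obj <- function(x) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) seen_out <<- TRUE
    -sum(x^2)
  }
  lumenreg:::de_optimize(obj, lo, hi, n_pop = 12, n_gen = 30, F = 0.9,
                         CR = 0.9, seed = 2)
  expect_false(seen_out)
})

test_that("coarse search shrinks the range around its solution", {
  obj <- function(x) -sum((x - c(5, 0, 0, 0, 0, 0))^2)
  rng <- search_range(rep(0, 6), rot_half = 10, trans_half = 10)
  cfg <- de_config(population_size = 16, max_iterations_coarse = 60, rng_seed = 3)
  out <- coarse_search(obj, rng, cfg)
  expect_equal(out$range$half, rng$half * cfg$fine_range_shrink, tolerance = 1e-12)
  b_new <- lumenreg:::range_bounds(out$range)
  b_old <- lumenreg:::range_bounds(rng)
  expect_true(all(b_new$lo >= b_old$lo - 1e-9))
  expect_true(all(b_new$hi <= b_old$hi + 1e-9))
  expect_lt(max(abs(pose_encode(out$pose) - c(5, 0, 0, 0, 0, 0))), 0.1)
})

test_that("a zero-width range returns the start pose with minimal work", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  gt <- scene$gt_poses[[ctx$view]]
  res <- register_views(scene, T0 = gt, range = search_range(gt, 1e-13, 1e-13),
                        cfg = de_config(rng_seed = 1), view = ctx$view,
                        aux_view = ctx$aux_view, context = ctx)
  expect_pose_equal(res$pose_fine, gt, 1e-6)
  expect_lte(res$evaluations, 2)
})

test_that("registration is deterministic end to end", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  gt <- scene$gt_poses[[ctx$view]]
  T0 <- perturb_pose(gt, search_range(gt, 15, 10), seed = 5)
  cfg <- de_config(population_size = 10, max_iterations_coarse = 6,
                   max_iterations_fine = 4, rng_seed = 9)
  r1 <- register_views(scene, T0 = T0, range = search_range(T0, 15, 10),
                       cfg = cfg, view = ctx$view, aux_view = ctx$aux_view,
                       context = ctx)
  r2 <- register_views(scene, T0 = T0, range = search_range(T0, 15, 10),
                       cfg = cfg, view = ctx$view, aux_view = ctx$aux_view,
                       context = ctx)
  expect_identical(unclass(r1$pose_fine), unclass(r2$pose_fine))
  expect_identical(r1$cost_trace, r2$cost_trace)
  expect_identical(r1$evaluations, r2$evaluations)
})

test_that("best-so-far cost traces are monotone within each stage", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  gt <- scene$gt_poses[[ctx$view]]
  T0 <- perturb_pose(gt, search_range(gt, 15, 10), seed = 2)
  cfg <- de_config(population_size = 12, max_iterations_coarse = 8,
                   max_iterations_fine = 6, rng_seed = 4)
  res <- register_views(scene, T0 = T0, range = search_range(T0, 15, 10),
                        cfg = cfg, view = ctx$view, aux_view = ctx$aux_view,
                        context = ctx)
  for (st in unique(res$cost_trace$stage)) {
    tr <- res$cost_trace$best_cost[res$cost_trace$stage == st]
    expect_true(all(diff(tr) >= 0), info = st)
  }
  # tidy/glance expose the trace and summary
  expect_identical(tidy(res), res$cost_trace)
  g <- glance(res)
  expect_identical(nrow(g), 1L)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("a pure position weighting reproduces a position-only fine search", {
  scene <- k2_scene()
  ctx <- protocol_context(scene, "k2")
  gt <- scene$gt_poses[[ctx$view]]
  cfg <- de_config(population_size = 8, max_iterations_fine = 5, rng_seed = 11)
  rng <- search_range(gt, 5, 3)
  f1 <- fine_search(lumenreg:::fine_objective(ctx, cost_weights(1, 0, 0)), rng, cfg)
  pos_only <- function(v) fine_cost(ctx, pose_decode(v), cost_weights(1, 0, 0))$c_pos
  f2 <- fine_search(pos_only, rng, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_pose_equal(f1$pose, f2$pose, 1e-12)
})
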