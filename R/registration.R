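#' Differential-evolution configuration
#'
#' rand/1/bin differential evolution over the 6-DOF pose box. Defaults
#' (population 30, 30 coarse / 30 fine generations, F = 0.7, CR = 0.9)
#' suit the standard +/-15 degree, +/-10 mm search range; the expanded
#' stress range benefits from more generations.
#'
#' @param population_size Population (>= 4).
#' @param max_iterations_coarse,max_iterations_fine Generation caps.
#' @param F Mutation factor (0, 2).
#' @param CR Crossover rate (0, 1].
#' @param strategy Coarse-stage strategy tag (`"rand/1/bin"`).
#' @param fine_strategy Fine-stage strategy: `"rand/1/bin"` (default) or
#'   `"best/1/bin"` (exploitative; converges faster but is prone to the
#'   plateau structure of the contour cost).
#' @param rng_seed Integer seed; the whole search is deterministic per seed.
#' @param tol Convergence tolerance on the best-cost change.
#' @param patience Generations without `tol` improvement to declare
#'   convergence.
#' @param fine_range_shrink Per-axis half-width factor applied between the
#'   coarse and fine stages.
#' @export
de_config <- function(population_size = 30, max_iterations_coarse = 30,
                      max_iterations_fine = 30, F = 0.7, CR = 0.9,
                      strategy = "rand/1/bin", fine_strategy = "rand/1/bin",
                      rng_seed = 1L,
                      tol = 1e-6, patience = 20L,
                      fine_range_shrink = c(0.7, 0.7, 0.7, 0.4, 0.4, 0.4)) {
  stopifnot(population_size >= 4, F > 0, F < 2, CR > 0, CR <= 1,
            identical(strategy, "rand/1/bin"),
            fine_strategy %in% c("rand/1/bin", "best/1/bin"), tol >= 0,
            all(fine_range_shrink > 0), all(fine_range_shrink <= 1),
            length(fine_range_shrink) %in% c(1L, 6L))
  structure(
    list(population_size = as.integer(population_size),
         max_iterations_coarse = as.integer(max_iterations_coarse),
         max_iterations_fine = as.integer(max_iterations_fine),
         F = F, CR = CR, strategy = strategy, fine_strategy = fine_strategy,
         rng_seed = as.integer(rng_seed),
         tol = tol, patience = as.integer(patience),
         fine_range_shrink = rep_len(fine_range_shrink, 6L)),
    class = "de_config"
  )
}

# DE maximization over a box; deterministic per seed.
# strategy "rand/1/bin" (exploratory) or "best/1/bin" (exploitative).
de_optimize <- function(objective, lo, hi, n_pop, n_gen, F, CR, seed,
                        tol = 1e-6, patience = 20L, strategy = "rand/1/bin",
                        init_center = NULL) {
  d <- length(lo)
  if (all(hi - lo < 1e-12)) {
    x <- (lo + hi) / 2
    return(list(best_x = x, best_f = objective(x), trace = objective(x),
                evaluations = 1L, converged = TRUE))
  }
  with_seed(seed, {
    pop <- matrix(runif(n_pop * d, rep(lo, each = n_pop), rep(hi, each = n_pop)),
                  n_pop, d)
    if (!is.null(init_center)) {
      # warm start: concentrate part of the population around the center
      # (the coarse solution), the rest stays exploratory over the box
      n_local <- floor(2 * n_pop / 3)
      half <- (hi - lo) / 2
      loc <- matrix(runif(n_local * d, -1, 1), n_local, d)
      loc <- sweep(loc, 2, half / 3, "*")
      loc <- sweep(loc, 2, init_center, "+")
      loc <- pmin(pmax(loc, matrix(lo, n_local, d, byrow = TRUE)),
                  matrix(hi, n_local, d, byrow = TRUE))
      pop[seq_len(n_local), ] <- loc
      pop[n_local + 1, ] <- pmin(pmax(init_center, lo), hi)
    }
    fit <- apply(pop, 1, objective)
    evals <- n_pop
    trace <- numeric(0)
    best_hist <- max(fit)
    stall <- 0L
    converged <- FALSE
    for (gen in seq_len(n_gen)) {
      for (i in seq_len(n_pop)) {
        idx <- sample(seq_len(n_pop)[-i], 3)
        base <- if (strategy == "best/1/bin") pop[which.max(fit), ] else pop[idx[1], ]
        v <- base + F * (pop[idx[2], ] - pop[idx[3], ])
        jrand <- sample.int(d, 1)
        u <- pop[i, ]
        mask <- runif(d) < CR
        mask[jrand] <- TRUE
        u[mask] <- v[mask]
        u <- pmin(pmax(u, lo), hi)
        fu <- objective(u)
        evals <- evals + 1L
        if (fu >= fit[i]) {
          pop[i, ] <- u
          fit[i] <- fu
        }
      }
      b <- max(fit)
      trace <- c(trace, b)
      if (b - best_hist < tol) stall <- stall + 1L else stall <- 0L
      best_hist <- max(best_hist, b)
      if (stall >= patience) { converged <- TRUE; break }
    }
    best <- which.max(fit)
    list(best_x = pop[best, ], best_f = fit[best], trace = trace,
         evaluations = evals, converged = converged)
  })
}

#' Build a registration context
#'
#' Precomputes everything pose-independent for one registration problem:
#' the salient point set, the actual contours of the chosen views (with
#' gradients attached, computed once and cached), the inter-frame motion
#' between the reference and auxiliary views, a visibility cache, and the
#' reduced-resolution render settings used to sample gradients for
#' generated contours.
#'
#' @param scene A `phantom_scene` (or a list with the same fields).
#' @param view Index of the reference view.
#' @param aux_view Indices of auxiliary views (one or more), or `NULL`
#'   for single-view registration. The multi-view cost term averages over
#'   them; two well-separated auxiliary frames suppress accidental
#'   contour matches more reliably than one.
#' @param F_set Optional precomputed `salient_point_set`.
#' @param sal_params A `salient_params`.
#' @param con_params A `contour_params`.
#' @param length_scale Pixel length scale of [position_cost()] during the
#'   coarse stage. The two stages form a scale hierarchy: the coarse
#'   stage matches at this coarser kernel (default 6 px, robust and
#'   smooth), the fine stage at a sharper one.
#' @param fine_length_scale Scale for the fine stage; `NULL` (default)
#'   uses `length_scale / 4` when the reference view provides a dense
#'   actual contour (>= 50 points), where the sharp kernel is
#'   identifiable, and `length_scale / 2` otherwise.
#' @param grad_render_width Width (px) of the reduced virtual render used
#'   to sample generated-contour gradients in the fine stage.
#' @param cache_pitch Translation grid pitch (mm) of the coarse-stage
#'   visibility cache.
#' @export
registration_context <- function(scene, view = 1L, aux_view = NULL,
                                 F_set = NULL,
                                 sal_params = salient_params(),
                                 con_params = contour_params(),
                                 length_scale = 6,
                                 fine_length_scale = NULL,
                                 grad_render_width = 64L,
                                 cache_pitch = 3) {
  mesh <- mesh_prepare(scene$mesh)
  if (is.null(F_set)) {
    F_set <- extract_salient_points(mesh, scene$vp, sal_params)
  }
  if (nrow(F_set$points) == 0) {
    stop("empty salient point set; enlarge vp or lower theta_T")
  }
  views <- lapply(c(view, aux_view), function(i) scene$views[[i]])
  actual <- lapply(views, function(v) {
    attach_gradients(extract_actual_contours(v$image, con_params), v$image)
  })
  # auxiliary frames without usable contours carry no constraint; drop them
  if (length(aux_view) > 0) {
    ok <- vapply(actual[-1], contour_size, integer(1)) >= 4L
    if (!all(ok)) {
      message("dropping ", sum(!ok), " auxiliary view(s) with <4 contour points")
      aux_view <- aux_view[ok]
      actual <- c(actual[1], actual[-1][ok])
    }
  }
  # frame(view) -> frame(aux) motions from the scene's stored chain
  t0n <- lapply(aux_view, function(i) {
    pose_compose(scene$relative_transforms[[i]],
                 pose_invert(scene$relative_transforms[[view]]))
  })
  if (length(t0n) == 0) t0n <- NULL
  intr <- scene$intrinsics
  f <- grad_render_width / intr$width
  grad_intr <- camera_intrinsics(
    fx = intr$fx * f, fy = intr$fy * f, cx = intr$cx * f, cy = intr$cy * f,
    width = max(16, round(intr$width * f)), height = max(16, round(intr$height * f))
  )
  structure(
    list(mesh = mesh, intr = intr, light = scene$lighting,
         F = F_set, theta_T = sal_params$theta_T,
         actual = actual, actual_grad = actual, t0n = t0n,
         view = as.integer(view),
         aux_view = as.integer(aux_view %||% integer(0)),
         length_scale = length_scale,
         fine_length_scale = fine_length_scale %||%
           if (contour_size(actual[[1]]) >= 50) length_scale / 4 else length_scale / 2,
         grad_intr = grad_intr, grad_scale = f,
         cache_pitch = cache_pitch, vis_cache = new.env(parent = emptyenv())),
    class = "registration_context"
  )
}

# Occlusion keep-vector over ctx$F from the (snapped) optical center,
# memoized on a translation grid -- rotation does not affect occlusion.
cached_visibility <- function(ctx, oc) {
  key <- paste(round(oc / ctx$cache_pitch), collapse = ",")
  hit <- ctx$vis_cache[[key]]
  if (!is.null(hit)) return(hit)
  snapped <- round(oc / ctx$cache_pitch) * ctx$cache_pitch
  occ <- segment_occluded(matrix(snapped, nrow(ctx$F$points), 3, byrow = TRUE),
                          ctx$F$points, ctx$mesh)
  ctx$vis_cache[[key]] <- !occ
  !occ
}

#' Generated contour for a candidate pose within a context
#'
#' Applies the perpendicularity / visibility / in-frame selection to the
#' context's salient set and projects the survivors. With
#' `exact_occlusion = FALSE` the occlusion test is looked up from the
#' translation-grid visibility cache (used by the coarse stage).
#'
#' @param ctx A `registration_context`.
#' @param pose Candidate `rigid_pose`.
#' @param exact_occlusion Exact per-pose occlusion (`TRUE`) or cached.
#' @return A `contour2d` (source `"generated"`).
#' @export
context_generated_contour <- function(ctx, pose, exact_occlusion = TRUE) {
  if (exact_occlusion) {
    P <- select_for_pose(ctx$F, pose, ctx$intr, ctx$mesh, ctx$theta_T)
    return(generate_contour(P, pose, ctx$intr))
  }
  oc <- camera_center(pose)
  vis <- cached_visibility(ctx, oc)
  Fv <- salient_point_set(ctx$F$points[vis, , drop = FALSE],
                          ctx$F$normals[vis, , drop = FALSE],
                          ctx$F$source_vertex_ids[vis])
  P <- select_for_pose(Fv, pose, ctx$intr, ctx$mesh, ctx$theta_T,
                       check_occlusion = FALSE)
  generate_contour(P, pose, ctx$intr)
}

# Coarse objective: location-based cost only (no gradient term), with the
# cheap cached-visibility contour generation. When an auxiliary view is
# available its position cost is included with the same relative weight as
# in the fine stage -- structure confusion between look-alike calyces makes
# the single-view position cost globally ambiguous, and the location term
# evaluated in a second frame resolves it.
coarse_objective <- function(ctx, weights = cost_weights()) {
  use_aux <- length(ctx$t0n) > 0 && weights$w3 > 0
  function(v) {
    pose <- pose_decode(v)
    gen <- context_generated_contour(ctx, pose, exact_occlusion = FALSE)
    if (contour_size(gen) == 0 || contour_size(ctx$actual[[1]]) == 0) return(0)
    cp <- weights$w1 * normalized_cost(
      position_cost(ctx$actual[[1]], gen, ctx$length_scale),
      contour_size(ctx$actual[[1]]), contour_size(gen)
    )
    if (use_aux) {
      parts <- vapply(seq_along(ctx$t0n), function(j) {
        pose_n <- auxiliary_view_pose(pose, ctx$t0n[[j]])
        gen_n <- context_generated_contour(ctx, pose_n, exact_occlusion = FALSE)
        act_n <- ctx$actual[[j + 1]]
        if (contour_size(gen_n) == 0 || contour_size(act_n) == 0) return(0)
        normalized_cost(position_cost(act_n, gen_n, ctx$length_scale),
                        contour_size(act_n), contour_size(gen_n))
      }, numeric(1))
      cp <- cp + weights$w3 * mean(parts)
    }
    cp
  }
}

fine_objective <- function(ctx, weights) {
  function(v) fine_cost(ctx, pose_decode(v), weights)$c_fine
}

#' Coarse search: position-only cost over the full range
#'
#' Differential-evolution maximization of the position similarity over
#' the 6-DOF box, followed by shrinking the box around the best pose
#' (half-widths scaled by `cfg$fine_range_shrink`, clipped to lie inside
#' the original box).
#'
#' @param objective Function of a 6-vector to maximize.
#' @param range A `search_range`.
#' @param cfg A `de_config`.
#' @return List with `pose`, `range` (shrunk), `trace`, `evaluations`,
#'   `converged`.
#' @export
coarse_search <- function(objective, range, cfg = de_config()) {
  b <- range_bounds(range)
  res <- de_optimize(objective, b$lo, b$hi, cfg$population_size,
                     cfg$max_iterations_coarse, cfg$F, cfg$CR,
                     cfg$rng_seed, cfg$tol, cfg$patience)
  half_new <- range$half * cfg$fine_range_shrink
  center <- pmin(pmax(res$best_x, b$lo + half_new), b$hi - half_new)
  shrunk <- structure(list(center = center, half = half_new),
                      class = "search_range")
  list(pose = pose_decode(res$best_x), range = shrunk, trace = res$trace,
       evaluations = res$evaluations, converged = res$converged)
}

#' Fine search: full cost over the shrunk range
#'
#' @param objective Function of a 6-vector to maximize (typically the
#'   weighted fine cost).
#' @param range The shrunk `search_range` from [coarse_search()].
#' @param cfg A `de_config`.
#' @return List with `pose`, `trace`, `evaluations`, `converged`.
#' @export
fine_search <- function(objective, range, cfg = de_config()) {
  b <- range_bounds(range)
  res <- de_optimize(objective, b$lo, b$hi, cfg$population_size,
                     cfg$max_iterations_fine, cfg$F, cfg$CR,
                     cfg$rng_seed + 1L, cfg$tol, cfg$patience,
                     strategy = cfg$fine_strategy %||% "rand/1/bin",
                     init_center = range$center)
  list(pose = pose_decode(res$best_x), trace = res$trace,
       evaluations = res$evaluations, converged = res$converged)
}

#' Register a camera view against the cavity model
#'
#' The full coarse-to-fine pipeline: extract actual contours once per
#' view, then (1) DE search of the position-only cost over the full
#' range, with generated contours continuously re-selected and
#' re-projected at each candidate pose; (2) DE search of the weighted
#' position + gradient + multi-view cost over the shrunk range.
#'
#' @param scene A `phantom_scene`.
#' @param T0 Start pose (`rigid_pose`); the search box is centered on it.
#' @param range A `search_range` (its center is overridden by `T0` unless
#'   `T0` is `NULL`).
#' @param cfg A `de_config`.
#' @param weights A `cost_weights` (set `w3 = 0` for single-view).
#' @param view,aux_view Reference / auxiliary view indices.
#' @param ... Passed to [registration_context()].
#' @param context Optional prebuilt `registration_context` (salient set
#'   and actual contours are then reused).
#' @return A `registration_result`.
#' @export
register_views <- function(scene, T0, range = search_range(T0),
                           cfg = de_config(), weights = cost_weights(),
                           view = 1L, aux_view = if (weights$w3 > 0) 2L else NULL,
                           context = NULL, ...) {
  if (weights$w3 > 0 && is.null(aux_view) && is.null(context)) {
    stop("multi-view weight w3 > 0 requires an aux_view")
  }
  ctx <- context %||% registration_context(scene, view = view,
                                           aux_view = aux_view, ...)
  if (!is.null(T0)) range <- structure(list(center = pose_encode(T0),
                                            half = range$half),
                                       class = "search_range")
  if (contour_size(ctx$actual[[1]]) == 0) {
    stop("no actual contour extracted from the reference view")
  }
  co <- coarse_search(coarse_objective(ctx, weights), range, cfg)
  fi <- fine_search(fine_objective(ctx, weights), co$range, cfg)
  trace <- tibble::tibble(
    stage = c(rep("coarse", length(co$trace)), rep("fine", length(fi$trace))),
    generation = c(seq_along(co$trace), seq_along(fi$trace)),
    best_cost = c(cummax(co$trace), cummax(fi$trace))
  )
  structure(
    list(pose_coarse = co$pose, pose_fine = fi$pose, cost_trace = trace,
         evaluations = co$evaluations + fi$evaluations,
         converged = fi$converged,
         config = list(de = unclass(cfg), weights = unclass(weights),
                       range_half = range$half, view = view,
                       aux_view = aux_view, length_scale = ctx$length_scale)),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  cat("  evaluations:", x$evaluations, " converged:", x$converged, "\n")
  cat("  final pose (rx ry rz tx ty tz):",
      paste(sprintf("%.2f", pose_encode(x$pose_fine)), collapse = " "), "\n")
  invisible(x)
}

#' Tidy methods for registration results
#'
#' `tidy()` returns the per-generation best-so-far cost trace;
#' `glance()` a one-row summary; `autoplot()` the cost trace by stage.
#'
#' @param x,object A `registration_result`.
#' @param ... Unused.
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
tidy.registration_result <- function(x, ...) x$cost_trace

#' @rdname tidy.registration_result
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(
    evaluations = x$evaluations,
    converged = x$converged,
    coarse_best = max(x$cost_trace$best_cost[x$cost_trace$stage == "coarse"]),
    fine_best = max(x$cost_trace$best_cost[x$cost_trace$stage == "fine"])
  )
}

#' @rdname tidy.registration_result
#' @export
autoplot.registration_result <- function(object, ...) {
  ggplot2::ggplot(object$cost_trace,
                  ggplot2::aes(x = .data$generation, y = .data$best_cost,
                               colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "DE generation", y = "best cost (maximized)",
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
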