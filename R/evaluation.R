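#' Mean target registration error
#'
#' Average displacement of the marker points between the ground-truth and
#' estimated transforms:
#' `mTRE = mean_i ||T_gt p_i - T_esti p_i||` with `p_i` in model (CT)
#' coordinates, mm.
#'
#' @param T_gt,T_esti `rigid_pose` objects.
#' @param markers n x 3 matrix of marker positions (model space, mm).
#' @return Scalar mm (attribute `"per_marker"` holds per-marker distances).
#' @export
mtre <- function(T_gt, T_esti, markers) {
  markers <- rbind3(markers)
  if (nrow(markers) == 0) stop("mtre requires at least one marker")
  d <- sqrt(rowSums((pose_apply(T_gt, markers) - pose_apply(T_esti, markers))^2))
  structure(mean(d), per_marker = d)
}

#' Orientation and position error between poses
#'
#' `orientation_error()` is the geodesic rotation angle of
#' `R_gt %*% t(R_esti)` in degrees; `position_error()` the Euclidean norm
#' of the pose translation difference in mm.
#'
#' @param T_gt,T_esti `rigid_pose` objects.
#' @export
orientation_error <- function(T_gt, T_esti) {
  R <- pose_rotation(T_gt) %*% t(pose_rotation(T_esti))
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' @rdname orientation_error
#' @export
position_error <- function(T_gt, T_esti) {
  sqrt(sum((pose_translation(T_gt) - pose_translation(T_esti))^2))
}

#' Mean distance from contour points to an oracle mask
#'
#' For each extracted contour point, the distance to the nearest `TRUE`
#' pixel (center) of the oracle mask; returns the mean in pixels. Used as
#' a plain mean-boundary-distance surrogate for contour quality.
#'
#' @param extracted A non-empty `contour2d`.
#' @param oracle_mask Logical matrix (e.g. from
#'   [silhouette_depth_edges()]) with at least one `TRUE`.
#' @return Scalar mean distance (px).
#' @export
contour_agreement <- function(extracted, oracle_mask) {
  if (contour_size(extracted) == 0) stop("empty contour")
  idx <- which(oracle_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty oracle mask")
  mask_pts <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)  # (u, v) pixel centers
  D <- pair_dist(extracted$points, mask_pts)
  mean(apply(D, 1, min))
}

#' Evaluate a registration result against ground truth
#'
#' @param result A `registration_result`.
#' @param T_gt Ground-truth `rigid_pose`.
#' @param markers n x 3 marker matrix.
#' @param T0 Optional start pose for the initial error.
#' @return Tibble with one row per stage (initial / coarse / fine):
#'   mtre, oe, pe.
#' @export
evaluate_registration <- function(result, T_gt, markers, T0 = NULL) {
  rows <- list()
  if (!is.null(T0)) {
    rows$initial <- c(mtre(T_gt, T0, markers), orientation_error(T_gt, T0),
                      position_error(T_gt, T0))
  }
  rows$coarse <- c(mtre(T_gt, result$pose_coarse, markers),
                   orientation_error(T_gt, result$pose_coarse),
                   position_error(T_gt, result$pose_coarse))
  rows$fine <- c(mtre(T_gt, result$pose_fine, markers),
                 orientation_error(T_gt, result$pose_fine),
                 position_error(T_gt, result$pose_fine))
  m <- do.call(rbind, rows)
  tibble::tibble(stage = names(rows), mtre = m[, 1], oe = m[, 2], pe = m[, 3])
}

#' Run a seeded perturb-register-evaluate trial suite
#'
#' Each trial perturbs the reference view's ground-truth pose within the
#' search range to obtain a start pose, runs the coarse-to-fine
#' registration from it, and evaluates mTRE / OE / PE. Failures of
#' individual trials are recorded (`NA` metrics) and the suite continues.
#'
#' @param scene A `phantom_scene` with at least 2 views for multi-view.
#' @param n_trials Number of trials.
#' @param range_half Length-2 `(rot_half_deg, trans_half_mm)` of the
#'   perturbation / search box.
#' @param cfg A `de_config`; trial `i` runs with `rng_seed + i`.
#' @param weights A `cost_weights`.
#' @param seed Base seed for the perturbations.
#' @param context Optional prebuilt `registration_context`.
#' @param ... Passed to [registration_context()] when `context` is `NULL`.
#' @return Tibble with one row per trial: seed, initial/coarse/final
#'   mtre, oe, pe, evaluations; summary mean/sd in attribute `"summary"`.
#' @export
trial_suite <- function(scene, n_trials = 10, range_half = c(15, 10),
                        cfg = de_config(), weights = cost_weights(),
                        seed = 0L, context = NULL, ...) {
  if (is.null(context)) {
    # reference frame: the view with the most extractable contour
    # structure, as an operator would choose; the others are auxiliary
    counts <- vapply(scene$views, function(v) {
      contour_size(extract_actual_contours(v$image))
    }, integer(1))
    ref <- which.max(counts)
    context <- registration_context(
      scene, view = ref,
      aux_view = if (weights$w3 > 0) setdiff(seq_along(scene$views), ref)
                 else NULL,
      ...
    )
  }
  ctx <- context
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    gt <- scene$gt_poses[[ctx$view]]
    rng <- search_range(gt, range_half[1], range_half[2])
    T0 <- perturb_pose(gt, rng, seed = seed + i)
    cfg_i <- cfg
    cfg_i$rng_seed <- cfg$rng_seed + i
    row <- tryCatch({
      res <- register_views(scene, T0 = T0,
                            range = search_range(T0, range_half[1], range_half[2]),
                            cfg = cfg_i, weights = weights, view = ctx$view,
                            aux_view = ctx$aux_view, context = ctx)
      ev <- evaluate_registration(res, gt, scene$markers, T0 = T0)
      tibble::tibble(
        trial = i, seed = seed + i,
        initial_mtre = ev$mtre[ev$stage == "initial"],
        coarse_mtre = ev$mtre[ev$stage == "coarse"],
        final_mtre = ev$mtre[ev$stage == "fine"],
        oe = ev$oe[ev$stage == "fine"], pe = ev$pe[ev$stage == "fine"],
        evaluations = res$evaluations, error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(trial = i, seed = seed + i, initial_mtre = NA_real_,
                     coarse_mtre = NA_real_, final_mtre = NA_real_,
                     oe = NA_real_, pe = NA_real_, evaluations = NA_integer_,
                     error = conditionMessage(e))
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  num <- out[, c("initial_mtre", "coarse_mtre", "final_mtre", "oe", "pe")]
  attr(out, "summary") <- tibble::tibble(
    metric = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(x) sd(x, na.rm = TRUE), numeric(1)),
    median = vapply(num, function(x) median(x, na.rm = TRUE), numeric(1))
  )
  out
}
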