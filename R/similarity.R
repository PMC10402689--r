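#' Weights of the fine-stage cost
#'
#' `c_fine = w1 * c_pos + w2 * c_grad + w3 * c_pos_aux` where `c_pos` is
#' the position similarity in the reference view, `c_grad` the gradient
#' similarity, and `c_pos_aux` the position similarity in the auxiliary
#' view. All costs are mutual-information-style scores that the optimizer
#' maximizes.
#'
#' Defaults give the reference-view position term and the multi-view
#' term equal weight: the auxiliary frames are what resolves the
#' depth/rotation ambiguity a single contour view leaves.
#'
#' @param w1,w2,w3 Non-negative weights, not all zero.
#' @export
cost_weights <- function(w1 = 0.4, w2 = 0.2, w3 = 0.4) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0, w1 + w2 + w3 > 0)
  structure(list(w1 = w1, w2 = w2, w3 = w3), class = "cost_weights")
}

# Mutual information of a joint built from pairwise affinities.
# W: n x m matrix of non-negative weights; normalized to a joint p_ij,
# MI = sum p_ij * ln(p_ij / (rowsum_i * colsum_j)). Natural log.
joint_mutual_information <- function(W) {
  s <- sum(W)
  if (!is.finite(s) || s <= 0) return(0)
  P <- W / s
  r <- rowSums(P)
  cs <- colSums(P)
  pos <- P > 0
  terms <- P[pos] * (log(P[pos]) - log(outer(r, cs))[pos])
  max(0, sum(terms))  # clamp -0.0 / tiny negative roundoff
}

#' Position similarity between two contours
#'
#' The joint-probability mutual information over pairwise distances:
#' `d_ij = |p_i - s_j| / length_scale`, `p_ij = exp(-d_ij) / sum(exp(-d))`,
#' `C_p = sum_ij p_ij * ln(p_ij / (rowsum_i colsum_j))` (natural log).
#' Non-negative; larger is better (the optimizer maximizes it). The
#' `length_scale` keeps the exponential in a useful numeric range for
#' pixel-scale distances.
#'
#' @param alpha,G `contour2d` objects (both non-empty).
#' @param length_scale Distance normalization in pixels.
#' @return Scalar `C_p >= 0`.
#' @export
position_cost <- function(alpha, G, length_scale = 20) {
  if (contour_size(alpha) == 0 || contour_size(G) == 0) {
    stop("no contour: position_cost requires non-empty point sets")
  }
  D <- pair_dist(alpha$points, G$points) / length_scale
  joint_mutual_information(exp(-D))
}

pair_dist <- function(A, B) {
  # n x m Euclidean distances
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(D2, 0))
}

#' Gradient similarity between two contours
#'
#' Affinities combine the gradient-magnitude difference
#' `m_ij = |mag_i - mag_j|` (each magnitude already in `[0, 1]`) and the
#' orientation difference folded to `[0, pi/2]` and normalized by `pi/2`:
#' `g_ij = exp(-(m_ij + o_ij))`, then the same mutual-information score as
#' [position_cost()].
#'
#' @param alpha,G `contour2d` objects carrying `grad_mag` / `grad_ori`.
#' @return Scalar `C_grad >= 0`.
#' @export
gradient_cost <- function(alpha, G) {
  if (is.null(alpha$grad_mag) || is.null(G$grad_mag) ||
      is.null(alpha$grad_ori) || is.null(G$grad_ori)) {
    stop("gradient attributes missing; call attach_gradients() first")
  }
  if (contour_size(alpha) == 0 || contour_size(G) == 0) {
    stop("no contour: gradient_cost requires non-empty point sets")
  }
  m <- abs(outer(alpha$grad_mag, G$grad_mag, "-"))
  dori <- abs(outer(alpha$grad_ori, G$grad_ori, "-"))
  o <- pmin(dori, pi - dori) / (pi / 2)
  joint_mutual_information(exp(-(m + o)))
}

#' Auxiliary-view pose from the reference pose and the inter-frame motion
#'
#' `T0n` is the rigid camera motion from frame 0 to frame n (for
#' model -> camera poses, `T0n = T_n_gt %*% solve(T_0_gt)`, the quantity a
#' tracking system measures between frames). The auxiliary pose for a
#' candidate reference pose `T0` is then `T_n = T0n %*% T0`, so that when
#' `T0` is the true frame-0 pose, rendering with `T_n` reproduces frame
#' n's viewpoint.
#'
#' @param T0 Candidate reference pose (`rigid_pose`).
#' @param T0n Frame-0-to-frame-n motion (`rigid_pose`).
#' @return The auxiliary `rigid_pose` `T_n`.
#' @export
auxiliary_view_pose <- function(T0, T0n) {
  pose_compose(T0n, T0)
}

# Size-weighted normalized MI used by the pose search. Raw joint MI is
# bounded by ln(min(n, m)): candidates seeing more salient points get a
# higher attainable score (a pull-back depth bias), while near-trivial
# joints of a handful of points saturate the bound (an accidental-match
# bias). The score divides by the bound and multiplies by the saturating
# confidence k / (k + k0), k = min(n, m), which rewards crisp AND ample
# matched structure; sets below `min_points` score 0.
normalized_cost <- function(raw, n, m, min_points = 3L, k0 = 10) {
  k <- min(n, m)
  if (k < min_points) return(0)
  raw / log(k) * k / (k + k0)
}

#' Cost breakdown of a fine-stage evaluation
#'
#' @param c_pos,c_grad,c_pos_aux Component scores (aux is 0 when unused).
#' @param weights A `cost_weights`.
#' @param n_alpha,n_G Contour sizes in the reference view.
#' @param degenerate `TRUE` when the candidate produced an empty generated
#'   contour and the cost was pinned to the worst value.
#' @export
cost_breakdown <- function(c_pos, c_grad, c_pos_aux, weights,
                           n_alpha = NA_integer_, n_G = NA_integer_,
                           degenerate = FALSE) {
  c_fine <- weights$w1 * c_pos + weights$w2 * c_grad + weights$w3 * c_pos_aux
  structure(
    list(c_pos = c_pos, c_grad = c_grad, c_pos_aux = c_pos_aux,
         c_fine = c_fine, n_alpha = n_alpha, n_G = n_G,
         degenerate = degenerate),
    class = "cost_breakdown"
  )
}

#' Evaluate the full fine-stage cost for a candidate pose
#'
#' Builds the generated contour for `pose` in the reference view (and,
#' when `weights$w3 > 0`, for [auxiliary_view_pose()] in the auxiliary
#' view), attaches gradients to the generated contour by sampling a
#' virtual rendering at the candidate pose, and combines the position,
#' gradient, and auxiliary-view position similarities. A candidate whose
#' generated contour is empty gets all components pinned to 0 (the worst
#' score for a maximizer) with `degenerate = TRUE` rather than an error,
#' so population-based search keeps running.
#'
#' @param ctx A registration context from [registration_context()].
#' @param pose Candidate `rigid_pose`.
#' @param weights A `cost_weights`.
#' @return A `cost_breakdown`.
#' @export
fine_cost <- function(ctx, pose, weights = cost_weights()) {
  gen <- context_generated_contour(ctx, pose, exact_occlusion = TRUE)
  if (contour_size(gen) == 0 || contour_size(ctx$actual[[1]]) == 0) {
    return(cost_breakdown(0, 0, 0, weights, contour_size(ctx$actual[[1]]),
                          0, degenerate = TRUE))
  }
  ls <- ctx$fine_length_scale %||% ctx$length_scale
  n1 <- contour_size(ctx$actual[[1]]); m1 <- contour_size(gen)
  c_pos <- normalized_cost(position_cost(ctx$actual[[1]], gen, ls), n1, m1)
  c_grad <- 0
  if (weights$w2 > 0) {
    rnd <- render_view(ctx$mesh, pose, ctx$grad_intr, ctx$light)
    gen_g <- attach_gradients(scale_contour(gen, ctx$grad_scale), rnd$image)
    gen_g$points <- gen$points  # gradients sampled at reduced resolution
    c_grad <- normalized_cost(gradient_cost(ctx$actual_grad[[1]], gen_g), n1, m1)
  }
  c_aux <- 0
  if (weights$w3 > 0 && length(ctx$t0n) > 0) {
    parts <- vapply(seq_along(ctx$t0n), function(j) {
      pose_n <- auxiliary_view_pose(pose, ctx$t0n[[j]])
      gen_n <- context_generated_contour(ctx, pose_n, exact_occlusion = TRUE)
      act_n <- ctx$actual[[j + 1]]
      if (contour_size(gen_n) == 0 || contour_size(act_n) == 0) return(0)
      normalized_cost(position_cost(act_n, gen_n, ls),
                      contour_size(act_n), contour_size(gen_n))
    }, numeric(1))
    c_aux <- mean(parts)
  }
  cost_breakdown(c_pos, c_grad, c_aux, weights,
                 contour_size(ctx$actual[[1]]), contour_size(gen))
}

scale_contour <- function(contour, f) {
  contour$points <- contour$points * f
  contour
}
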