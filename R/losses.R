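#' Cycle-consistency loss of an unpaired image-translation pair
#'
#' For generator maps `G_st` (source -> target style) and `G_ts`, the
#' mean absolute reconstruction error of both round trips:
#' `E|G_ts(G_st(x)) - x|_1 + E|G_st(G_ts(y)) - y|_1`, with expectations
#' taken as arithmetic means over the batches. Zero iff both compositions
#' are exact identities on the batches.
#'
#' These loss functions are pure array computations: they document and
#' test the translation objective itself; no network training is
#' performed by this package.
#'
#' @param G_st,G_ts Shape-preserving functions from image to image.
#' @param batch_s,batch_t Lists of numeric arrays in `[0, 1]`.
#' @return Scalar loss (>= 0).
#' @export
cycle_loss <- function(G_st, G_ts, batch_s, batch_t) {
  l1 <- function(batch, Ga, Gb) {
    mean(vapply(batch, function(x) {
      y <- Gb(Ga(x))
      if (!identical(dim(y) %||% length(y), dim(x) %||% length(x))) {
        stop("generator changed the image shape")
      }
      mean(abs(y - x))
    }, numeric(1)))
  }
  l1(batch_s, G_st, G_ts) + l1(batch_t, G_ts, G_st)
}

#' Adversarial (GAN) losses
#'
#' One direction: `E[ln D_t(y)] + E[ln(1 - D_t(G_st(x)))]` with natural
#' logs; discriminator outputs are clamped to `[1e-7, 1 - 1e-7]`.
#' `adversarial_loss_total()` sums both directions.
#'
#' @param G_st,G_ts Generator functions.
#' @param D_t,D_s Discriminator functions returning values in (0, 1)
#'   (scalar or per-pixel arrays; arrays are averaged).
#' @param batch_s,batch_t Lists of arrays.
#' @return Scalar loss (<= 0; 0 is the perfect-discriminator supremum).
#' @export
adversarial_loss <- function(G_st, D_t, batch_s, batch_t) {
  clamp <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  real <- mean(vapply(batch_t, function(y) mean(log(clamp(D_t(y)))), numeric(1)))
  fake <- mean(vapply(batch_s, function(x) mean(log(1 - clamp(D_t(G_st(x))))),
                      numeric(1)))
  real + fake
}

#' @rdname adversarial_loss
#' @export
adversarial_loss_total <- function(G_st, G_ts, D_t, D_s, batch_s, batch_t) {
  adversarial_loss(G_st, D_t, batch_s, batch_t) +
    adversarial_loss(G_ts, D_s, batch_t, batch_s)
}

#' Semantic-consistency (K-way cross-entropy) task loss
#'
#' Mean per-pixel cross-entropy of the segmenter's softmax on the
#' translated image against reference per-pixel labels:
#' `-mean(ln softmax(u_s(G(x)))[label])`. `semantic_loss_total()` sums
#' the two translation directions.
#'
#' @param u_s Function image -> H x W x K logit array.
#' @param G Generator function.
#' @param batch List of images.
#' @param reference_masks List of H x W integer label matrices in `1..K`.
#' @return Scalar loss (>= 0).
#' @export
semantic_task_loss <- function(u_s, G, batch, reference_masks) {
  stopifnot(length(batch) == length(reference_masks))
  mean(mapply(function(x, lab) {
    logits <- u_s(G(x))
    stopifnot(length(dim(logits)) == 3)
    K <- dim(logits)[3]
    if (any(lab < 1 | lab > K)) stop("label outside 1..", K)
    mx <- apply(logits, c(1, 2), max)
    lse <- mx + log(apply(exp(logits - as.vector(mx)), c(1, 2), sum))
    h <- dim(logits)[1]; w <- dim(logits)[2]
    picked <- logits[cbind(rep(seq_len(h), w), rep(seq_len(w), each = h),
                           as.vector(lab))]
    mean(lse - matrix(picked, h, w))
  }, batch, reference_masks))
}

#' @rdname semantic_task_loss
#' @export
semantic_loss_total <- function(u_s, G_st, G_ts, batch_s, batch_t,
                                masks_s, masks_t) {
  semantic_task_loss(u_s, G_st, batch_s, masks_s) +
    semantic_task_loss(u_s, G_ts, batch_t, masks_t)
}

#' Total translation objective
#'
#' `L_all = L_base + L_sem` with `L_base = L_cyc + L_GAN`: a pure sum of
#' the component losses, no hidden weights.
#'
#' @param cycle,gan,semantic Component losses.
#' @return Scalar.
#' @export
total_loss <- function(cycle, gan, semantic = 0) {
  stopifnot(is.finite(cycle), is.finite(gan), is.finite(semantic))
  cycle + gan + semantic
}
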