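#' 2D contour point sets
#'
#' An unordered set of 2D pixel coordinates, optionally with per-point
#' gradient magnitude (normalized to `[0, 1]`) and orientation (radians in
#' `[0, pi)`), tagged as `"actual"` (extracted from an image) or
#' `"generated"` (projected salient points).
#'
#' @param points n x 2 matrix of (u, v) pixel coordinates.
#' @param grad_mag,grad_ori Optional length-n numeric vectors.
#' @param source `"actual"` or `"generated"`.
#' @export
contour2d <- function(points, grad_mag = NULL, grad_ori = NULL,
                      source = c("actual", "generated")) {
  source <- match.arg(source)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (!is.null(grad_mag)) stopifnot(length(grad_mag) == nrow(points))
  if (!is.null(grad_ori)) stopifnot(length(grad_ori) == nrow(points))
  structure(list(points = unname(points), grad_mag = grad_mag,
                 grad_ori = grad_ori, source = source),
            class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("<contour2d: %s> %d points%s\n", x$source, nrow(x$points),
              if (!is.null(x$grad_mag)) " (+gradients)" else ""))
  invisible(x)
}

#' Number of points in a contour
#' @param c A `contour2d`.
#' @export
contour_size <- function(c) nrow(c$points)

#' Parameters for actual-contour extraction
#'
#' Defaults are stated for 400 x 400 images; `n_superpixels` and `tau_n`
#' scale with image area (see [extract_actual_contours()]).
#'
#' @param n_superpixels Target superpixel count (>= 2).
#' @param compactness SLIC compactness (intensity units on the 0-255
#'   scale per superpixel-grid interval).
#' @param tau_gc Minimum superpixel-vs-neighbor mean intensity contrast,
#'   on the 0-255 scale.
#' @param tau_n Minimum pixel count of a selected superpixel.
#' @param use_abs_diff Select on `max |l_diff|` (`TRUE`) or on the signed
#'   maximum (`FALSE`).
#' @param require_darker Additionally require the superpixel to be darker
#'   than its brightest neighbor (structural contours are shadowed
#'   recesses).
#' @export
contour_params <- function(n_superpixels = 400, compactness = 10,
                           tau_gc = 30, tau_n = 30,
                           use_abs_diff = TRUE, require_darker = TRUE) {
  stopifnot(n_superpixels >= 2, tau_gc > 0, tau_n >= 1, compactness > 0)
  structure(
    list(n_superpixels = as.integer(n_superpixels), compactness = compactness,
         tau_gc = tau_gc, tau_n = as.integer(tau_n),
         use_abs_diff = isTRUE(use_abs_diff),
         require_darker = isTRUE(require_darker)),
    class = "contour_params"
  )
}

# The superpixel COUNT is kept constant across image sizes (superpixels
# should partition the scene, not the pixel grid), while the size
# threshold tau_n scales with the expected superpixel area relative to
# the 400x400 reference (where 400 superpixels have ~400 px each).
scale_contour_params <- function(params, width, height) {
  sp_area <- (width * height) / params$n_superpixels
  params$tau_n <- max(1L, as.integer(round(params$tau_n * sp_area / 400)))
  params
}

#' SLIC superpixel segmentation
#'
#' Deterministic grayscale SLIC (grid seeding, 10 k-means iterations,
#' connectivity enforcement). The image is rescaled to 0-255 internally
#' so `compactness` has the conventional meaning.
#'
#' @param image Matrix in `[0, 1]` (or any range; rescaled).
#' @param params A `contour_params`; `n_superpixels` is used as requested
#'   (no area scaling here).
#' @return Integer label matrix (labels 1..K, every pixel assigned).
#' @export
superpixel_segment <- function(image, params = contour_params()) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 8 || ncol(image) < 8) stop("image smaller than 8x8")
  rng <- range(image, finite = TRUE)
  img255 <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) * 255 else image * 0
  slic_cpp(img255, params$n_superpixels, params$compactness, 10L)
}

superpixel_adjacency <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  # 8-connectivity between regions: collect label pairs across pixel edges
  pairs <- rbind(
    cbind(as.vector(labels[-h, ]), as.vector(labels[-1, ])),        # vertical
    cbind(as.vector(labels[, -w]), as.vector(labels[, -1])),        # horizontal
    cbind(as.vector(labels[-h, -w]), as.vector(labels[-1, -1])),    # diag \
    cbind(as.vector(labels[-h, -1]), as.vector(labels[-1, -w]))     # diag /
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  unique(rbind(pairs, pairs[, 2:1]))
}

#' Extract actual contours from a 2D image
#'
#' The superpixel contrast rule: segment the image with SLIC, compute each
#' superpixel's pixel count and mean intensity (0-255 scale), find the
#' maximum mean-intensity difference to its 8-adjacent neighbors, and
#' select superpixels whose contrast reaches `tau_gc` and whose size
#' reaches `tau_n` (by default also requiring the region to be darker
#' than its brightest neighbor). The returned contour points are the
#' barycenters of the selected superpixels.
#'
#' @param image Matrix in `[0, 1]`.
#' @param params A `contour_params`. `n_superpixels` and `tau_n` refer to
#'   a 400 x 400 image and are scaled by relative image area.
#' @return A `contour2d` with source `"actual"` (possibly empty).
#' @export
extract_actual_contours <- function(image, params = contour_params()) {
  sp <- scale_contour_params(params, ncol(image), nrow(image))
  labels <- superpixel_segment(image, sp)
  contours_from_labels(image, labels, sp)
}

# selection rule given a precomputed label map (params already area-scaled)
contours_from_labels <- function(image, labels, sp) {
  img255 <- image * 255
  lab <- as.vector(labels)
  n_sp <- tabulate(lab)
  sum_i <- tabulate2(lab, as.vector(img255), max(lab))
  mean_i <- sum_i / pmax(n_sp, 1)
  adj <- superpixel_adjacency(labels)
  if (nrow(adj) == 0) return(contour2d(matrix(0, 0, 2), source = "actual"))
  ldiff <- mean_i[adj[, 1]] - mean_i[adj[, 2]]  # l_sp0 - l_neb
  # signed variant follows the literal rule max(l_sp0 - l_neb) >= tau_gc
  key <- if (sp$use_abs_diff) abs(ldiff) else ldiff
  max_contrast <- tapply2(key, adj[, 1], max, length(n_sp), -Inf)
  brightest_nb <- tapply2(mean_i[adj[, 2]], adj[, 1], max, length(n_sp), -Inf)
  sel <- max_contrast >= sp$tau_gc & n_sp >= sp$tau_n
  if (sp$require_darker) sel <- sel & mean_i < brightest_nb
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) return(contour2d(matrix(0, 0, 2), source = "actual"))
  # barycenters (u = column - 0.5 -> pixel-center coordinates)
  vv <- matrix(seq_len(nrow(image)) - 0.5, nrow(image), ncol(image))
  uu <- matrix(rep(seq_len(ncol(image)) - 0.5, each = nrow(image)), nrow(image))
  bu <- tapply2(as.vector(uu), lab, mean, length(n_sp), NA_real_)
  bv <- tapply2(as.vector(vv), lab, mean, length(n_sp), NA_real_)
  contour2d(cbind(bu[sel], bv[sel]), source = "actual")
}

tapply2 <- function(x, idx, fn, n, fill) {
  out <- rep(fill, n)
  agg <- vapply(split(x, idx), fn, numeric(1))
  out[as.integer(names(agg))] <- agg
  out
}

#' Sobel gradient magnitude and orientation maps
#'
#' Magnitude is normalized to `[0, 1]` by its image maximum (all zeros for
#' a flat image); orientation is `atan2(gv, gu)` folded to `[0, pi)`.
#'
#' @param image Matrix in `[0, 1]`.
#' @return List with `magnitude` and `orientation` matrices.
#' @export
image_gradients <- function(image) {
  gu <- convolve3x3(image, rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1)))
  gv <- convolve3x3(image, rbind(c(-1, -2, -1), c(0, 0, 0), c(1, 2, 1)))
  mag <- sqrt(gu^2 + gv^2)
  mx <- max(mag)
  # guard against pure floating-point residue on flat images
  if (mx > 1e-12) mag <- mag / mx else mag[] <- 0
  ori <- atan2(gv, gu) %% pi
  list(magnitude = mag, orientation = ori)
}

convolve3x3 <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (dy in -1:1) {
    for (dx in -1:1) {
      kv <- k[dy + 2, dx + 2]
      if (kv == 0) next
      ys <- pmin(pmax(seq_len(h) + dy, 1), h)
      xs <- pmin(pmax(seq_len(w) + dx, 1), w)
      out <- out + kv * img[ys, xs, drop = FALSE]
    }
  }
  out
}

#' Attach image gradients to a contour
#'
#' Samples the Sobel maps of `image` at the contour points by bilinear
#' interpolation (pixel centers at half-integer coordinates) and fills
#' `grad_mag` / `grad_ori`. Re-attaching overwrites.
#'
#' @param contour A `contour2d`.
#' @param image Matrix in `[0, 1]`.
#' @param gradients Optional precomputed [image_gradients()] output.
#' @return The contour with gradient fields set.
#' @export
attach_gradients <- function(contour, image, gradients = NULL) {
  g <- gradients %||% image_gradients(image)
  if (nrow(contour$points) == 0) {
    contour$grad_mag <- numeric(0); contour$grad_ori <- numeric(0)
    return(contour)
  }
  contour$grad_mag <- bilinear_sample(g$magnitude, contour$points)
  # orientation interpolated via its doubled-angle unit vector (circular)
  cs <- bilinear_sample(cos(2 * g$orientation), contour$points)
  sn <- bilinear_sample(sin(2 * g$orientation), contour$points)
  contour$grad_ori <- (atan2(sn, cs) / 2) %% pi
  contour
}

bilinear_sample <- function(mat, pts) {
  h <- nrow(mat); w <- ncol(mat)
  # pixel (i, j) center at u = j - 0.5, v = i - 0.5
  x <- pmin(pmax(pts[, 1] + 0.5, 1), w)
  y <- pmin(pmax(pts[, 2] + 0.5, 1), h)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  idx <- function(i, j) mat[cbind(i, j)]
  v00 <- idx(y0, x0); v01 <- idx(y0, x0 + 1)
  v10 <- idx(y0 + 1, x0); v11 <- idx(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Contour CSV I/O
#'
#' Columns: u, v, grad_mag, grad_ori, source.
#'
#' @param contour A `contour2d`.
#' @param path CSV path.
#' @export
write_contour <- function(contour, path) {
  n <- nrow(contour$points)
  df <- data.frame(
    u = contour$points[, 1], v = contour$points[, 2],
    grad_mag = contour$grad_mag %||% rep(NA_real_, n),
    grad_ori = contour$grad_ori %||% rep(NA_real_, n),
    source = rep(contour$source, n)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  df <- read.csv(path)
  gm <- if (all(is.na(df$grad_mag))) NULL else df$grad_mag
  go <- if (all(is.na(df$grad_ori))) NULL else df$grad_ori
  contour2d(cbind(df$u, df$v), gm, go,
            source = if (nrow(df)) as.character(df$source[1]) else "actual")
}
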