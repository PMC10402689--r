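#' Phong lighting parameters for the virtual endoscopy renderer
#'
#' The light is a headlight co-located with the optical center, the
#' standard single-scope illumination geometry. Shading per hit:
#' `ambient + att * (diffuse * max(0, n.l) + specular * max(0, r.v)^shininess)`
#' with distance attenuation
#' `att = 1 / (constant + linear * d + quadratic * d^2)` (d in mm).
#' Defaults are chosen so that a cavity wall at ~10 mm renders mid-bright
#' while calyx interiors beyond ~30 mm fall toward black, imitating the
#' rapid light falloff of a small endoscope light source.
#'
#' @param ambient,diffuse,specular Coefficients in `[0, 1]`.
#' @param shininess Specular exponent (> 0).
#' @param constant,linear,quadratic Attenuation coefficients (per mm).
#' @export
lighting_params <- function(ambient = 0.03, diffuse = 1.0, specular = 0.25,
                            shininess = 24, constant = 1.0, linear = 0.01,
                            quadratic = 0.006) {
  stopifnot(
    ambient >= 0, ambient <= 1, diffuse >= 0, diffuse <= 1,
    specular >= 0, specular <= 1, shininess > 0,
    constant > 0, linear >= 0, quadratic >= 0
  )
  structure(
    list(ambient = ambient, diffuse = diffuse, specular = specular,
         shininess = shininess, constant = constant, linear = linear,
         quadratic = quadratic),
    class = "lighting_params"
  )
}

#' Render an interior view of a cavity mesh
#'
#' Software per-pixel ray casting: for each pixel the nearest triangle hit
#' is shaded with the Phong headlight model of [lighting_params()] using
#' barycentrically interpolated vertex normals (flipped toward the viewer,
#' so the interior surface of inward- or outward-wound meshes renders
#' identically). Pixels whose ray misses the mesh are 0 in the image and
#' `Inf` in the depth map.
#'
#' @param mesh A `tri_mesh`.
#' @param pose A `rigid_pose` (model -> camera).
#' @param intr A `camera_intrinsics`.
#' @param light A `lighting_params`.
#' @return A list with `image` (height x width matrix in `[0, 1]`) and
#'   `depth` (height x width, hit distance in mm, `Inf` on miss).
#' @export
render_view <- function(mesh, pose, intr, light = lighting_params()) {
  if (nrow(mesh$faces) == 0 || nrow(mesh$vertices) == 0) {
    return(list(
      image = matrix(0, intr$height, intr$width),
      depth = matrix(Inf, intr$height, intr$width)
    ))
  }
  res <- render_view_cpp(
    mesh_accel(mesh), mesh$normals, unclass(pose),
    intr$fx, intr$fy, intr$cx, intr$cy, intr$width, intr$height,
    light$ambient, light$diffuse, light$specular, light$shininess,
    light$constant, light$linear, light$quadratic
  )
  list(image = res$image, depth = res$depth)
}

#' Depth-discontinuity (silhouette) edge mask
#'
#' Marks pixels whose 8-neighborhood depth range exceeds `jump_threshold`.
#' Serves as the geometric oracle for where image contours should lie:
#' occlusion boundaries (calyx rims seen against deeper wall) are exactly
#' the depth jumps.
#'
#' @param depth Depth map from [render_view()] (mm; `Inf` allowed).
#' @param jump_threshold Depth jump in mm.
#' @return Logical matrix of the same size.
#' @export
silhouette_depth_edges <- function(depth, jump_threshold = 3) {
  h <- nrow(depth); w <- ncol(depth)
  dmax <- matrix(-Inf, h, w); dmin <- matrix(Inf, h, w)
  for (dy in -1:1) {
    for (dx in -1:1) {
      ys <- pmin(pmax(seq_len(h) + dy, 1), h)
      xs <- pmin(pmax(seq_len(w) + dx, 1), w)
      sh <- depth[ys, xs, drop = FALSE]
      dmax <- pmax(dmax, sh)
      dmin <- pmin(dmin, sh)
    }
  }
  jump <- dmax - dmin
  jump[!is.finite(jump)] <- Inf  # Inf-depth next to finite counts as a jump
  all_miss <- !is.finite(dmin)   # fully-background neighborhoods are not edges
  mask <- jump > jump_threshold & !all_miss
  mask
}

#' Read / write grayscale images
#'
#' Thin wrappers over the `png` package; images are `[0, 1]` matrices
#' (rows = image v/y, columns = u/x).
#'
#' @param image Matrix in `[0, 1]`.
#' @param path PNG file path.
#' @export
write_image <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img
}
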