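#' Axis-aligned ellipsoid volumes
#'
#' Used for the pelvic search volume `Vp` (candidate camera positions are
#' drawn from it, and the tangent-plane intersection test of the salient
#' point extractor is evaluated against it).
#'
#' @param center Length-3 center (mm).
#' @param semi_axes Length-3 positive semi-axes (mm).
#' @export
ellipsoid <- function(center = c(0, 0, 0), semi_axes = c(1, 1, 1)) {
  stopifnot(length(center) == 3, length(semi_axes) == 3, all(semi_axes > 0))
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes)),
            class = "ellipsoid")
}

#' @param e An `ellipsoid`.
#' @param points n x 3 matrix.
#' @rdname ellipsoid
#' @export
ellipsoid_contains <- function(e, points) {
  p <- sweep(rbind3(points), 2, e$center)
  rowSums(sweep(p, 2, e$semi_axes, "/")^2) <= 1
}

#' Specification of a synthetic branched cavity
#'
#' Describes a renal-pelvis-like cavity: a central ellipsoidal chamber
#' (semi-axes `pelvis_radius * c(1, 0.85, 0.7)`) from which `n_calyces`
#' tubular lobes branch radially. The surface is star-shaped around the
#' chamber center, built as a radial displacement field on a subdivided
#' icosphere, which guarantees a watertight genus-0 mesh.
#'
#' @param pelvis_radius Chamber base radius (mm).
#' @param n_calyces Number of branching lobes (>= 1; 0 allowed for a plain
#'   chamber).
#' @param calyx_radius_range Range of lobe tube radii (mm; below
#'   `pelvis_radius`).
#' @param calyx_length_range Range of lobe lengths beyond the chamber (mm).
#' @param branch_angles `"random"` or a matrix with columns azimuth and
#'   elevation (degrees), one row per calyx.
#' @param mesh_resolution Target edge length (mm); controls icosphere
#'   subdivision.
#' @param rng_seed Integer seed making the geometry deterministic.
#' @export
scene_spec <- function(pelvis_radius = 15, n_calyces = 4,
                       calyx_radius_range = c(4, 7),
                       calyx_length_range = c(10, 20),
                       branch_angles = "random",
                       mesh_resolution = 2.5, rng_seed = 1L) {
  stopifnot(pelvis_radius > 0, n_calyces >= 0, mesh_resolution > 0,
            max(calyx_radius_range) < pelvis_radius,
            min(calyx_radius_range) > 0, min(calyx_length_range) > 0)
  structure(
    list(pelvis_radius = pelvis_radius, n_calyces = as.integer(n_calyces),
         calyx_radius_range = calyx_radius_range,
         calyx_length_range = calyx_length_range,
         branch_angles = branch_angles,
         mesh_resolution = mesh_resolution, rng_seed = as.integer(rng_seed)),
    class = "scene_spec"
  )
}

#' Canned fixture specs
#'
#' `scene_spec_k1()` is the "complex" fixture (6 calyces on two elevation
#' levels); `scene_spec_k2()` the "simple" one (3 calyces, one level).
#' Dimensions are free choices on the scale of an adult renal collecting
#' system (chamber ~15 mm, calyces 4-8 mm radius).
#' @rdname scene_spec
#' @export
scene_spec_k1 <- function(mesh_resolution = 2) {
  # calyces fan toward one side of the pelvis in upper / interpolar /
  # lower groups, as in a coronal view of a collecting system; the
  # opposite wall stays smooth, as the ureteropelvic side does
  scene_spec(
    pelvis_radius = 15, n_calyces = 6,
    calyx_radius_range = c(4, 6.5), calyx_length_range = c(11, 20),
    branch_angles = cbind(
      azimuth = c(20, 75, 0, 60, 30, 85),
      elevation = c(55, 38, 3, -8, -52, -30)
    ),
    mesh_resolution = mesh_resolution, rng_seed = 101L
  )
}

#' @rdname scene_spec
#' @export
scene_spec_k2 <- function(mesh_resolution = 2) {
  # irregular tripod: spacings and elevations all differ, as they do in a
  # simple collecting system (no two calyces are interchangeable)
  scene_spec(
    pelvis_radius = 15, n_calyces = 3,
    calyx_radius_range = c(4.5, 8), calyx_length_range = c(9, 17),
    branch_angles = cbind(azimuth = c(0, 105, 230), elevation = c(38, 10, 27)),
    mesh_resolution = mesh_resolution, rng_seed = 202L
  )
}

# unit icosphere with `level` subdivisions, faces wound CCW-outward
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  V <- V / sqrt(rowSums(V^2))
  F_ <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (l in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      m <- (V[i, ] + V[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1]] <<- m
      id <- nv + length(newV)
      mid_cache[[key]] <- id
      id
    }
    newF <- matrix(0L, nrow(F_) * 4, 3)
    for (f in seq_len(nrow(F_))) {
      a <- F_[f, 1]; b <- F_[f, 2]; c_ <- F_[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newF[(f - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca)
      )
    }
    V <- rbind(V, do.call(rbind, newV))
    F_ <- newF
  }
  list(V = V, F = F_)
}

# Resolve calyx axes/radii/lengths for a spec (deterministic).
calyx_layout <- function(spec) {
  n <- spec$n_calyces
  if (n == 0) {
    return(list(axes = matrix(0, 0, 3), radius = numeric(0), length = numeric(0),
                sigma = numeric(0)))
  }
  with_seed(spec$rng_seed, {
    if (identical(spec$branch_angles, "random")) {
      # rejection-sample axes with pairwise separation >= 50 deg
      axes <- matrix(0, 0, 3)
      tries <- 0
      while (nrow(axes) < n && tries < 10000) {
        tries <- tries + 1
        u <- runif(1, -1, 1); a <- runif(1, 0, 2 * pi)
        d <- c(sqrt(1 - u^2) * cos(a), sqrt(1 - u^2) * sin(a), u)
        if (nrow(axes) == 0 || all(axes %*% d < cos(50 * pi / 180))) {
          axes <- rbind(axes, d)
        }
      }
      if (nrow(axes) < n) stop("could not place ", n, " calyces 50 deg apart")
    } else {
      ba <- spec$branch_angles * pi / 180
      axes <- cbind(cos(ba[, 2]) * cos(ba[, 1]), cos(ba[, 2]) * sin(ba[, 1]),
                    sin(ba[, 2]))
    }
    radius <- runif(n, spec$calyx_radius_range[1], spec$calyx_radius_range[2])
    len <- runif(n, spec$calyx_length_range[1], spec$calyx_length_range[2])
    # angular half-width giving roughly the requested tube radius at the rim
    sigma <- atan2(radius, spec$pelvis_radius)
    # azimuthal cross-section irregularity (real calyces are not circular);
    # 2nd/3rd harmonic modulation of the lobe half-width around its axis
    amp2 <- runif(n, 0.10, 0.25)
    amp3 <- runif(n, 0.05, 0.15)
    ph2 <- runif(n, 0, 2 * pi)
    ph3 <- runif(n, 0, 2 * pi)
    list(axes = axes, radius = radius, length = len, sigma = sigma,
         amp2 = amp2, amp3 = amp3, ph2 = ph2, ph3 = ph3)
  })
}

# orthonormal in-plane frame (u, v) of a calyx axis, shared by the radius
# field and the rim-curve oracle
calyx_frame <- function(a) {
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- cross3(a, ref); u <- u / sqrt(sum(u^2))
  list(u = u, v = cross3(a, u))
}

calyx_width_modulation <- function(layout, k, azimuth) {
  1 + layout$amp2[k] * cos(2 * azimuth - layout$ph2[k]) +
    layout$amp3[k] * cos(3 * azimuth - layout$ph3[k])
}

chamber_semi_axes <- function(spec) spec$pelvis_radius * c(1, 0.85, 0.7)

# radial surface function r(d) for unit directions d (n x 3)
cavity_radius <- function(dirs, spec, layout) {
  ax <- chamber_semi_axes(spec)
  r <- 1 / sqrt(rowSums(sweep(dirs, 2, ax, "/")^2))
  if (nrow(layout$axes) > 0) {
    for (k in seq_len(nrow(layout$axes))) {
      a <- layout$axes[k, ]
      cosang <- pmin(1, pmax(-1, dirs %*% a))
      psi <- acos(cosang)
      fr <- calyx_frame(a)
      az <- atan2(dirs %*% fr$v, dirs %*% fr$u)
      sig <- layout$sigma[k] * calyx_width_modulation(layout, k, az)
      # exponent 6: tube-like lobe with a crisp junction crease, closer to
      # the sharp infundibulum transition of a CT-derived surface
      r <- r + layout$length[k] * exp(-(psi / sig)^6)
    }
  }
  as.numeric(r)
}

#' Generate a watertight branched-cavity mesh
#'
#' Builds the star-shaped surface described by [scene_spec()]: a
#' subdivided icosphere whose vertices are pushed to the radial distance
#' of the chamber-plus-lobes displacement field. Faces are wound so vertex
#' normals point into the lumen. Deterministic given `spec$rng_seed`.
#'
#' @param spec A `scene_spec`.
#' @return A `tri_mesh`.
#' @export
make_branched_cavity <- function(spec) {
  layout <- calyx_layout(spec)
  rmax <- spec$pelvis_radius + if (length(layout$length)) max(layout$length) else 0
  level <- min(6, max(2, ceiling(log2(1.0515 * rmax / spec$mesh_resolution))))
  ico <- icosphere(level)
  r <- cavity_radius(ico$V, spec, layout)
  V <- ico$V * r
  # flip winding: CCW from outside -> CCW from inside (inward normals)
  F_ <- ico$F[, c(1, 3, 2)]
  mesh <- tri_mesh(V, F_)
  attr(mesh, "layout") <- layout
  attr(mesh, "spec") <- spec
  mesh
}

#' Junction rim curves of a generated cavity
#'
#' For each calyx, points on the chamber-lobe junction curve: where a
#' tube of the calyx's radius around its axis would intersect the
#' chamber ellipsoid (`sin(psi) * r_chamber(d) = calyx_radius`, solved
#' per azimuth by fixed-point iteration). Salient structural points are
#' expected to concentrate along these curves.
#'
#' @param mesh A mesh from [make_branched_cavity()].
#' @param n_per_rim Points per rim circle.
#' @return m x 3 matrix of rim points (mm), with a `calyx` attribute.
#' @export
junction_rims <- function(mesh, n_per_rim = 72) {
  layout <- attr(mesh, "layout", exact = TRUE)
  spec <- attr(mesh, "spec", exact = TRUE)
  stopifnot(!is.null(layout), !is.null(spec))
  ax <- chamber_semi_axes(spec)
  r_e <- function(d) 1 / sqrt(sum((d / ax)^2))
  out <- NULL; tag <- integer(0)
  for (k in seq_len(nrow(layout$axes))) {
    a <- layout$axes[k, ]
    fr <- calyx_frame(a)
    u <- fr$u; v <- fr$v
    th <- seq(0, 2 * pi, length.out = n_per_rim + 1)[-(n_per_rim + 1)]
    dirs <- t(vapply(th, function(t_) {
      lat <- cos(t_) * u + sin(t_) * v
      rho <- layout$radius[k] * calyx_width_modulation(layout, k, t_)
      psi <- asin(min(0.95, rho / r_e(a)))
      for (it in 1:3) {  # fixed point: sin(psi) r_e(d) = rho
        d <- cos(psi) * a + sin(psi) * lat
        psi <- asin(min(0.95, rho / r_e(d)))
      }
      d <- cos(psi) * a + sin(psi) * lat
      d / sqrt(sum(d^2))
    }, numeric(3)))
    pts <- dirs * cavity_radius(dirs, spec, layout)
    out <- rbind(out, pts)
    tag <- c(tag, rep(k, n_per_rim))
  }
  attr(out, "calyx") <- tag
  out
}

#' Place evaluation markers around a cavity
#'
#' Samples `n` points on a +`offset` mm inflated copy of the surface
#' (area-weighted face sampling, displaced along the outward normal),
#' mimicking target markers distributed around a printed phantom.
#' Candidates whose true distance to the surface falls below
#' `0.9 * offset` (concave exterior pockets) are rejected.
#'
#' @param mesh A closed `tri_mesh` with inward normals.
#' @param n Number of markers.
#' @param seed Integer seed.
#' @param offset Outward offset in mm.
#' @return n x 3 matrix of marker positions (mm).
#' @export
place_markers <- function(mesh, n = 10, seed = 1L, offset = 5) {
  V <- mesh$vertices; F_ <- mesh$faces
  e1 <- V[F_[, 2], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  e2 <- V[F_[, 3], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(fn^2)) / 2
  inward <- fn / (2 * area)  # unit face normals (inward winding)
  with_seed(seed, {
    out <- matrix(0, 0, 3)
    guard <- 0
    while (nrow(out) < n && guard < 10000) {
      guard <- guard + 1
      f <- sample.int(nrow(F_), 1, prob = area)
      r1 <- runif(1); r2 <- runif(1)
      if (r1 + r2 > 1) { r1 <- 1 - r1; r2 <- 1 - r2 }
      p <- V[F_[f, 1], ] + r1 * e1[f, ] + r2 * e2[f, ]
      cand <- p - offset * inward[f, ]  # outward = -inward
      if (distance_to_surface(cand, mesh) >= 0.9 * offset) {
        out <- rbind(out, cand)
      }
    }
    if (nrow(out) < n) stop("marker placement failed after 10000 draws")
    unname(out)
  })
}

look_at_pose <- function(center, target, roll_deg = 0) {
  d <- target - center
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x0 <- cross3(d, ref); x0 <- x0 / sqrt(sum(x0^2))
  y0 <- cross3(d, x0)
  phi <- roll_deg * pi / 180
  x <- cos(phi) * x0 + sin(phi) * y0
  y <- -sin(phi) * x0 + cos(phi) * y0
  R <- rbind(x, y, d)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- -R %*% center
  rigid_pose(reproject_rigid(m))
}

#' Sample ground-truth endoscope poses inside a cavity
#'
#' Optical centers are drawn uniformly from the pelvic volume `vp`
#' (rejection sampling, with an inside-lumen parity check against the
#' mesh); each camera aims at the mouth of a randomly chosen calyx, so
#' depth (distance to the aimed opening) and roll (uniform in
#' `[-180, 180)`) vary across samples, emulating an endoscope surveying
#' the calyces.
#'
#' @param mesh A mesh from [make_branched_cavity()].
#' @param vp An `ellipsoid` search volume inside the lumen.
#' @param n_poses Number of poses.
#' @param seed Integer seed.
#' @return List of `rigid_pose` (model -> camera).
#' @export
sample_gt_poses <- function(mesh, vp, n_poses, seed = 1L) {
  layout <- attr(mesh, "layout", exact = TRUE)
  spec <- attr(mesh, "spec", exact = TRUE)
  stopifnot(!is.null(layout), nrow(layout$axes) >= 1)
  with_seed(seed, {
    poses <- vector("list", n_poses)
    made <- 0; guard <- 0
    while (made < n_poses) {
      guard <- guard + 1
      if (guard > 10000) stop("pose sampling failed after 10000 draws")
      c_ <- vp$center + runif(3, -1, 1) * vp$semi_axes
      if (!ellipsoid_contains(vp, c_)) next
      if (!points_inside_mesh(c_, mesh)) next
      k <- sample.int(nrow(layout$axes), 1)
      a <- layout$axes[k, ]
      depth_frac <- runif(1, 0.15, 0.7)  # aim point depth into the calyx
      fr <- calyx_frame(a)
      jaz <- runif(1, 0, 2 * pi)         # lateral aim jitter: off-center view
      jmag <- runif(1, 0.2, 0.6) * layout$radius[k]
      aim <- a * (spec$pelvis_radius * 0.8 + depth_frac * layout$length[k]) +
        jmag * (cos(jaz) * fr$u + sin(jaz) * fr$v)
      if (sqrt(sum((aim - c_)^2)) < 9) next  # standoff: keep the mouth framed
      # oblique approach only: a stare down the calyx axis shows a
      # featureless dark disk, which no operator would use for
      # registration; the required obliquity scales with the mouth's
      # angular half-width so wide mouths are viewed from the side
      vdir <- (aim - c_) / sqrt(sum((aim - c_)^2))
      min_off <- max(18, layout$sigma[k] * 180 / pi + 8)
      if (sum(vdir * a) > cos(min_off * pi / 180)) next
      roll <- runif(1, -180, 180)
      p <- look_at_pose(c_, aim, roll)
      made <- made + 1
      poses[[made]] <- p
    }
    poses
  })
}

#' Search ranges for the 6-DOF pose optimization
#'
#' A box in the pose encoding `(rx, ry, rz, tx, ty, tz)` (degrees / mm)
#' centered on a start pose. The defaults mirror a +/-15 degree, +/-10 mm
#' clinical initialization uncertainty; the expanded stress protocol uses
#' +/-90 degrees, +/-30 mm.
#'
#' @param center A `rigid_pose` or a length-6 encoding vector.
#' @param rot_half Per-axis rotation half-width (degrees).
#' @param trans_half Per-axis translation half-width (mm).
#' @export
search_range <- function(center, rot_half = 15, trans_half = 10) {
  mu <- if (inherits(center, "rigid_pose")) pose_encode(center) else as.numeric(center)
  stopifnot(length(mu) == 6, all(rot_half >= 0), all(trans_half >= 0))
  half <- c(rep_len(rot_half, 3), rep_len(trans_half, 3))
  structure(list(center = mu, half = half), class = "search_range")
}

range_bounds <- function(range) {
  list(lo = range$center - range$half, hi = range$center + range$half)
}

#' Perturb a ground-truth pose within a search range
#'
#' Adds a uniform offset (per axis, within the range half-widths) to the
#' pose's 6-vector encoding. With zero half-widths the pose is returned
#' unchanged. The drawn offset is recorded in attribute `"offset"`.
#'
#' @param gt A `rigid_pose`.
#' @param range A `search_range` (its `center` is ignored; only the
#'   half-widths are used).
#' @param seed Integer seed.
#' @export
perturb_pose <- function(gt, range, seed = 1L) {
  with_seed(seed, {
    offset <- runif(6, -1, 1) * range$half
    out <- pose_decode(pose_encode(gt) + offset)
    attr(out, "offset") <- offset
    out
  })
}

#' Assemble a complete synthetic phantom scene
#'
#' Generates the cavity mesh, ten exterior markers, a pelvic search
#' volume, `n_poses` ground-truth endoscope poses, rendered views with
#' depth maps, and the inter-frame motions
#' `relative_transforms[[n]] = T_n %*% solve(T_0)` (identity for n = 1)
#' used by the multi-view cost.
#'
#' @param spec A `scene_spec`.
#' @param n_poses Number of ground-truth poses/views.
#' @param intr A `camera_intrinsics` (default 200 x 200, 90 degree FOV).
#' @param light A `lighting_params`.
#' @param seed Integer seed for markers and poses.
#' @param n_markers Number of evaluation markers.
#' @return An object of class `phantom_scene`.
#' @export
build_scene <- function(spec, n_poses = 5,
                        intr = camera_intrinsics(fx = 100, width = 200, height = 200),
                        light = lighting_params(), seed = 1L, n_markers = 10) {
  mesh <- mesh_prepare(make_branched_cavity(spec))
  vp <- ellipsoid(c(0, 0, 0), 0.55 * chamber_semi_axes(spec))
  markers <- place_markers(mesh, n = n_markers, seed = seed + 1L)
  gt_poses <- sample_gt_poses(mesh, vp, n_poses, seed = seed + 2L)
  views <- lapply(gt_poses, function(p) render_view(mesh, p, intr, light))
  t0_inv <- pose_invert(gt_poses[[1]])
  rel <- lapply(gt_poses, function(p) pose_compose(p, t0_inv))
  structure(
    list(spec = spec, mesh = mesh, vp = vp, markers = markers,
         gt_poses = gt_poses, views = views, relative_transforms = rel,
         intrinsics = intr, lighting = light, seed = as.integer(seed)),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %d calyces, %d faces, %d markers, %d views (%dx%d)\n",
    x$spec$n_calyces, nrow(x$mesh$faces), nrow(x$markers),
    length(x$views), x$intrinsics$width, x$intrinsics$height
  ))
  invisible(x)
}

#' Write / read a scene directory
#'
#' Layout: `mesh.ply`, `markers.csv` (x, y, z in mm),
#' `poses/pose_NNN.json`, `views/view_NNN.png`, and a `scene.yaml`
#' manifest (spec, search volume, relative transforms, camera, lighting).
#'
#' @param scene A `phantom_scene`.
#' @param dir Output directory (created).
#' @export
save_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "poses"), showWarnings = FALSE)
  dir.create(file.path(dir, "views"), showWarnings = FALSE)
  write_mesh(scene$mesh, file.path(dir, "mesh.ply"))
  write.csv(setNames(as.data.frame(scene$markers), c("x", "y", "z")),
            file.path(dir, "markers.csv"), row.names = FALSE)
  for (i in seq_along(scene$gt_poses)) {
    write_pose(scene$gt_poses[[i]],
               file.path(dir, "poses", sprintf("pose_%03d.json", i - 1)))
    png::writePNG(scene$views[[i]]$image,
                  file.path(dir, "views", sprintf("view_%03d.png", i - 1)))
  }
  manifest <- list(
    schema = "lumenreg-scene-1",
    spec = unclass(scene$spec),
    vp = list(center = scene$vp$center, semi_axes = scene$vp$semi_axes),
    intrinsics = unclass(scene$intrinsics),
    lighting = unclass(scene$lighting),
    seed = scene$seed,
    relative_transforms = lapply(scene$relative_transforms,
                                 function(p) as.numeric(t(unclass(p))))
  )
  manifest$spec$branch_angles <-
    if (identical(scene$spec$branch_angles, "random")) "random"
    else as.numeric(scene$spec$branch_angles)
  yaml::write_yaml(manifest, file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' @rdname save_scene
#' @export
load_scene <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  sp <- man$spec
  if (!identical(sp$branch_angles, "random")) {
    sp$branch_angles <- matrix(as.numeric(sp$branch_angles), ncol = 2)
    colnames(sp$branch_angles) <- c("azimuth", "elevation")
  }
  spec <- scene_spec(sp$pelvis_radius, sp$n_calyces,
                     as.numeric(sp$calyx_radius_range),
                     as.numeric(sp$calyx_length_range),
                     sp$branch_angles, sp$mesh_resolution, sp$rng_seed)
  mesh <- mesh_prepare(make_branched_cavity(spec))  # regenerated: carries layout
  pose_files <- sort(list.files(file.path(dir, "poses"), full.names = TRUE))
  gt_poses <- lapply(pose_files, read_pose)
  view_files <- sort(list.files(file.path(dir, "views"), full.names = TRUE))
  intr <- do.call(camera_intrinsics, man$intrinsics)
  light <- do.call(lighting_params, man$lighting)
  views <- lapply(seq_along(gt_poses), function(i) {
    img <- png::readPNG(view_files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    depth <- render_view(mesh, gt_poses[[i]], intr, light)$depth
    list(image = img, depth = depth)
  })
  rel <- lapply(man$relative_transforms, function(v) {
    rigid_pose(reproject_rigid(matrix(as.numeric(v), 4, 4, byrow = TRUE)))
  })
  markers <- as.matrix(read.csv(file.path(dir, "markers.csv")))
  dimnames(markers) <- NULL
  structure(
    list(spec = spec, mesh = mesh, vp = ellipsoid(as.numeric(man$vp$center),
                                                  as.numeric(man$vp$semi_axes)),
         markers = markers, gt_poses = gt_poses, views = views,
         relative_transforms = rel, intrinsics = intr, lighting = light,
         seed = man$seed),
    class = "phantom_scene"
  )
}
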