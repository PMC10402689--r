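flat_wall <- function(z = 10, half = 100, tilt_deg = 0) {
  # large quad perpendicular to the optical axis, optionally tilted about x
  V <- rbind(c(-half, -half, 0), c(half, -half, 0),
             c(half, half, 0), c(-half, half, 0))
  a <- tilt_deg * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  V <- V %*% t(R)
  V[, 3] <- V[, 3] + z
  tri_mesh(V, rbind(c(1, 2, 3), c(1, 3, 4)))
}

# principal point on the center pixel's center so the middle ray is on-axis
plain_intr <- camera_intrinsics(fx = 50, fy = 50, cx = 24.5, cy = 24.5,
                                width = 50, height = 50)
no_att <- lighting_params(ambient = 0, diffuse = 1, specular = 0,
                          shininess = 1, constant = 1, linear = 0, quadratic = 0)

test_that("empty mesh renders black with infinite depth", {
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(integer(0), 0, 3),
                          normals = matrix(0, 0, 3)), class = "tri_mesh")
  out <- render_view(empty, pose_identity(), plain_intr, no_att)
  expect_true(all(out$image == 0))
  expect_true(all(is.infinite(out$depth)))
})

test_that("Phong headlight shading follows the cosine law", {
  out <- render_view(flat_wall(z = 10), pose_identity(), plain_intr, no_att)
  cc <- 25  # center pixel
  expect_equal(out$image[cc, cc], 1, tolerance = 1e-3)
  expect_equal(out$depth[cc, cc], 10, tolerance = 1e-6)

  out60 <- render_view(flat_wall(z = 10, tilt_deg = 60), pose_identity(),
                       plain_intr, no_att)
  expect_equal(out60$image[cc, cc], cos(60 * pi / 180), tolerance = 5e-3)
})

test_that("intensity decreases with distance under attenuation only", {
  att <- lighting_params(ambient = 0, diffuse = 1, specular = 0,
                         shininess = 1, constant = 1, linear = 0.05,
                         quadratic = 0.01)
  vals <- vapply(c(5, 10, 20, 40), function(z) {
    render_view(flat_wall(z = z), pose_identity(), plain_intr, att)$image[25, 25]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("depth map equals brute-force closest-triangle search", {
  ico <- lumenreg:::icosphere(0)       # 20 triangles
  mesh <- tri_mesh(ico$V * 8, ico$F[, c(1, 3, 2)])
  intr <- camera_intrinsics(fx = 16, fy = 16, cx = 16, cy = 16,
                            width = 32, height = 32)
  out <- render_view(mesh, pose_identity(), intr, no_att)
  for (v in seq(1, 32, by = 5)) {
    for (u in seq(1, 32, by = 5)) {
      d <- c((u - 0.5 - 16) / 16, (v - 0.5 - 16) / 16, 1)
      d <- d / sqrt(sum(d^2))
      best <- Inf
      for (f in seq_len(nrow(mesh$faces))) {
        t <- oracle_ray_triangle(c(0, 0, 0), d,
                                 mesh$vertices[mesh$faces[f, 1], ],
                                 mesh$vertices[mesh$faces[f, 2], ],
                                 mesh$vertices[mesh$faces[f, 3], ])
        if (!is.na(t)) best <- min(best, t)
      }
      expect_equal(out$depth[v, u], best, tolerance = 1e-9)
    }
  }
})

test_that("rendering is deterministic and clipped to [0, 1]", {
  mesh <- sphere_cavity(r = 10)
  light <- lighting_params(ambient = 0.5, diffuse = 1, specular = 1, shininess = 2)
  a <- render_view(mesh, pose_identity(), plain_intr, light)
  b <- render_view(mesh, pose_identity(), plain_intr, light)
  expect_identical(a$image, b$image)
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("depth-discontinuity mask marks steps and only steps", {
  expect_true(all(!silhouette_depth_edges(matrix(10, 40, 40), 3)))
  # two parallel walls with a straight vertical step at column 20
  depth <- cbind(matrix(10, 40, 20), matrix(20, 40, 20))
  mask <- silhouette_depth_edges(depth, 3)
  cols <- unique(which(mask, arr.ind = TRUE)[, 2])
  expect_setequal(cols, c(20, 21))
  expect_true(all(!silhouette_depth_edges(depth, 15)))
})

test_that("images survive a PNG round trip", {
  img <- matrix(seq(0, 1, length.out = 900), 30, 30)
  path <- tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_lt(max(abs(back - img)), 1 / 255)
})
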