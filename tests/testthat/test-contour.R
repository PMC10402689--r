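test_that("SLIC partitions every pixel into roughly the requested count", {
  img <- matrix(0.5, 80, 80)
  labels <- superpixel_segment(img, contour_params(n_superpixels = 16))
  expect_identical(dim(labels), dim(img))
  expect_true(all(labels >= 1))
  k <- max(labels)
  expect_gte(k, 8); expect_lte(k, 24)          # within +/-50% of 16
  expect_equal(sort(unique(as.vector(labels))), 1:k)
  expect_error(superpixel_segment(matrix(0, 4, 4), contour_params()), "8x8")
})

test_that("SLIC respects a high-contrast boundary", {
  img <- cbind(matrix(0.1, 80, 40), matrix(0.9, 80, 40))
  labels <- superpixel_segment(img, contour_params(n_superpixels = 64))
  # boundary recall at 2 px: label changes across columns 39..42
  crossings <- labels[, 39:42]
  changed <- apply(crossings, 1, function(r) length(unique(r)) > 1)
  expect_gte(mean(changed), 0.9)
  # no superpixel mixes the two tones badly
  means <- tapply(as.vector(img), as.vector(labels), mean)
  expect_true(all(means < 0.35 | means > 0.65))
})

test_that("contrast selection finds a dark disk and nothing in flat images", {
  expect_equal(contour_size(extract_actual_contours(matrix(0.5, 100, 100))), 0)
  # dark disk (intensity 20/255, radius 12) on bright background (220/255)
  img <- matrix(220 / 255, 100, 100)
  for (v in 1:100) for (u in 1:100) {
    if ((u - 50)^2 + (v - 50)^2 <= 144) img[v, u] <- 20 / 255
  }
  ac <- extract_actual_contours(img, contour_params(tau_gc = 50, tau_n = 20))
  expect_gt(contour_size(ac), 0)
  bc <- colMeans(ac$points)
  expect_lt(sqrt(sum((bc - c(49.5, 49.5))^2)), 3)
  # unattainable threshold on the 8-bit range selects nothing
  expect_equal(contour_size(extract_actual_contours(img, contour_params(tau_gc = 256))), 0)
})

test_that("selection counts are monotone in both thresholds", {
  img <- k2_scene()$views[[1]]$image
  n_tau <- vapply(c(10, 20, 30, 45, 60), function(tg) {
    contour_size(extract_actual_contours(img, contour_params(tau_gc = tg)))
  }, numeric(1))
  expect_true(all(diff(n_tau) <= 0))
  n_size <- vapply(c(5, 15, 30, 60, 120), function(tn) {
    contour_size(extract_actual_contours(img, contour_params(tau_n = tn)))
  }, numeric(1))
  expect_true(all(diff(n_size) <= 0))
})

test_that("relabeling superpixels does not change the extracted points", {
  img <- k2_scene()$views[[1]]$image
  sp <- lumenreg:::scale_contour_params(contour_params(), ncol(img), nrow(img))
  labels <- superpixel_segment(img, sp)
  a <- lumenreg:::contours_from_labels(img, labels, sp)
  perm <- sample(max(labels))
  relabeled <- matrix(perm[labels], nrow(labels))
  b <- lumenreg:::contours_from_labels(img, relabeled, sp)
  expect_equal(a$points[order(a$points[, 1], a$points[, 2]), ],
               b$points[order(b$points[, 1], b$points[, 2]), ],
               tolerance = 1e-12)
})

test_that("Sobel gradients recover analytic orientations", {
  expect_true(all(image_gradients(matrix(0.7, 30, 30))$magnitude == 0))
  # vertical step edge: gradient along +u, orientation ~ 0
  img <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  g <- image_gradients(img)
  band <- g$orientation[5:35, 20:21]
  expect_true(all(pmin(band, pi - band) < 1e-9))
  expect_equal(max(g$magnitude), 1)
  # 45-degree diagonal ramp: orientation ~ pi/4 in the interior
  ramp <- outer(1:40, 1:40, function(i, j) (i + j) / 80)
  g2 <- image_gradients(ramp)
  interior <- g2$orientation[5:35, 5:35]
  expect_lt(max(abs(interior - pi / 4)), 1e-6)
})

test_that("gradient attachment samples the maps and is idempotent", {
  flat <- matrix(0.3, 50, 50)
  c0 <- contour2d(cbind(c(10, 25), c(10, 40)))
  c1 <- attach_gradients(c0, flat)
  expect_equal(c1$grad_mag, c(0, 0))
  img <- cbind(matrix(0, 50, 25), matrix(1, 50, 25))
  on_edge <- attach_gradients(contour2d(matrix(c(24.5, 25), 1)), img)
  expect_gt(on_edge$grad_mag, 0.9)
  again <- attach_gradients(on_edge, img)
  expect_identical(again$grad_mag, on_edge$grad_mag)
  expect_identical(again$grad_ori, on_edge$grad_ori)
})

test_that("contours round-trip through CSV", {
  c0 <- contour2d(cbind(c(1.5, 2.5), c(3.5, 4.5)), grad_mag = c(0.1, 0.9),
                  grad_ori = c(0.3, 2.7), source = "actual")
  path <- tempfile(fileext = ".csv")
  write_contour(c0, path)
  back <- read_contour(path)
  expect_equal(back$points, c0$points)
  expect_equal(back$grad_mag, c0$grad_mag)
  expect_identical(back$source, "actual")
})
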