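test_that("images round-trip through PNG and RGB collapses to luminance", {
  tmp <- withr::local_tempdir()
  img <- matrix(128, 64, 64)
  p <- file.path(tmp, "const.png")
  write_grey_image(img, p)
  expect_identical(load_image(p), img)

  rgb <- array(50 / 255, dim = c(32, 32, 3))
  p2 <- file.path(tmp, "rgb.png")
  png::writePNG(rgb, p2)
  expect_true(all(load_image(p2) == 50))

  ph <- make_phantom(phantom_spec(canvas = c(96, 96), r0 = 25,
                                  speckle_sigma = 0.1, seed = 5))
  p3 <- file.path(tmp, "phantom.png")
  write_grey_image(ph$image, p3)
  expect_identical(load_image(p3), ph$image)

  expect_error(load_image(file.path(tmp, "missing.png")), "not found")
  png::writePNG(matrix(0.5, 4, 4), file.path(tmp, "tiny.png"))
  expect_error(load_image(file.path(tmp, "tiny.png")), "at least 8x8")
})

test_that("contours round-trip through JSON", {
  tmp <- withr::local_tempdir()
  v <- cbind(row = c(10, 10, 40, 40), col = c(10, 40, 40, 10))
  p <- file.path(tmp, "c.json")
  write_contour(v, p)
  back <- read_contour(p)
  expect_equal(unname(back), unname(v), tolerance = 1e-6)
})

test_that("rasterization fills polygons with inclusive boundaries", {
  sq <- cbind(c(10, 10, 40, 40), c(10, 40, 40, 10))
  mask <- rasterize_contour(sq, c(50, 50))
  expect_equal(sum(mask), 31 * 31)

  th <- 2 * pi * (0:359) / 360
  circ <- cbind(60 + 30 * sin(th), 60 + 30 * cos(th))
  cmask <- rasterize_contour(circ, c(120, 120))
  expect_lt(abs(sum(cmask) - pi * 30^2) / (pi * 30^2), 0.02)
  # against the crossing-number oracle (few vertex pixels may sit on edges)
  cnt <- 0
  for (i in 25:95) for (j in 25:95) {
    if (oracle_point_in_polygon(circ, i, j)) cnt <- cnt + 1
  }
  expect_lte(abs(sum(cmask) - cnt), 8)

  tri <- cbind(c(1, 1, 11), c(1, 11, 1))
  tmask <- rasterize_contour(tri, c(20, 20))
  expect_equal(sum(tmask), 66)

  expect_error(rasterize_contour(cbind(c(-1, 5, 5), c(1, 1, 5)), c(20, 20)),
               "outside")
  expect_error(rasterize_contour(cbind(c(1, 2), c(1, 2)), c(20, 20)),
               "at least 3")
  expect_error(rasterize_contour(cbind(c(1, 5, 9), c(1, 1, 1)), c(20, 20)),
               "zero area")
})

test_that("boundary tracing is clockwise, 8-connected, and matches the
           brute-force inner boundary", {
  sq <- cbind(c(10, 10, 40, 40), c(10, 40, 40, 10))
  mask <- rasterize_contour(sq, c(50, 50))
  b <- trace_boundary(mask)
  expect_equal(nrow(b), 120)  # 4*31 - 4

  # single-pixel-wide mask rejected
  thin <- matrix(FALSE, 20, 20); thin[10, 5:15] <- TRUE
  expect_error(trace_boundary(thin), "simple closed|degenerate|short")
  expect_error(trace_boundary(matrix(FALSE, 10, 10)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(trace_boundary(two), "one component")

  for (s in c(3, 9, 21)) {
    m <- random_phantom_roi(s)$roi$mask
    tb <- trace_boundary(m)
    expect_setequal((tb[, 2] - 1) * nrow(m) + tb[, 1], oracle_inner_boundary(m))
    steps <- cbind(diff(tb[, 1]), diff(tb[, 2]))
    expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))
    x <- tb[, 2]; y <- tb[, 1]
    expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y), 0)  # clockwise
  }
})

test_that("centroid is the mean foreground coordinate", {
  sq <- rasterize_contour(cbind(c(10, 10, 40, 40), c(10, 40, 40, 10)), c(50, 50))
  expect_equal(unname(mask_centroid(sq)), c(25, 25))

  m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m[1, 3] <- TRUE
  expect_equal(unname(mask_centroid(m)), c(1, 2))

  blob <- random_phantom_roi(4)$roi$mask
  idx <- which(blob, arr.ind = TRUE)
  expect_equal(unname(mask_centroid(blob)),
               c(sum(idx[, 1]) / nrow(idx), sum(idx[, 2]) / nrow(idx)))
  expect_error(mask_centroid(matrix(FALSE, 4, 4)), "empty")
})

test_that("radial sequences carry distances and angles in clockwise order", {
  th <- 2 * pi * (0:719) / 720
  circ <- cbind(64 + 50 * sin(th), 64 + 50 * cos(th))
  mask <- rasterize_contour(circ, c(128, 128))
  b <- trace_boundary(mask)
  rs <- to_radial_sequence(b, mask_centroid(mask))
  # inner boundary of a centre-inside fill: radii within one pixel below r0
  expect_true(all(rs$r >= 49 & rs$r <= 50.5))
  expect_equal(rs$n, nrow(b))
  expect_true(all(rs$theta >= 0 & rs$theta < 2 * pi))

  sq <- rasterize_contour(cbind(c(20, 20, 80, 80), c(20, 80, 80, 20)), c(100, 100))
  rsq <- to_radial_sequence(trace_boundary(sq), mask_centroid(sq))
  expect_lt(abs(max(rsq$r) / min(rsq$r) - sqrt(2)), 0.03 * sqrt(2))

  expect_error(to_radial_sequence(cbind(5, 5), c(5, 5)), "zero radius|short")
})

test_that("geometry is translation invariant and rasterize-trace is idempotent", {
  base <- random_phantom_roi(7)$roi
  # shift the mask in a larger canvas
  big <- matrix(FALSE, 160, 160)
  idx <- which(base$mask, arr.ind = TRUE)
  big[cbind(idx[, 1] + 5, idx[, 2] + 7)] <- TRUE
  img <- matrix(100, 160, 160)
  roi2 <- lesion_roi(img, mask = big)
  expect_equal(roi2$S, base$S)
  expect_equal(roi2$C, base$C)
  rs1 <- to_radial_sequence(base$boundary, base$centroid)
  rs2 <- to_radial_sequence(roi2$boundary, roi2$centroid)
  expect_equal(sort(rs2$r), sort(rs1$r), tolerance = 1e-12)

  # rasterize -> trace -> rasterize reaches a fixed point after one round trip
  m1 <- rasterize_contour(trace_boundary(base$mask), dim(base$mask))
  m2 <- rasterize_contour(trace_boundary(m1), dim(m1))
  expect_identical(m1, m2)

  expect_lte(base$C, base$S)
})

test_that("lesion_roi validates its inputs", {
  img <- matrix(100, 64, 64)
  expect_error(lesion_roi(img), "contour or a mask")
  bad <- matrix(FALSE, 64, 64); bad[5:10, 5:10] <- TRUE; bad[40:45, 40:45] <- TRUE
  expect_error(lesion_roi(img, mask = bad), "one component")
  expect_error(lesion_roi(matrix(300, 64, 64),
                          mask = matrix(TRUE, 64, 64)), "0, 255")
})
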