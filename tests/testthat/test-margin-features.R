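test_that("margin spicules follow the spectral ratio and its overflow case", {
  # analytically constant radii: all mass at DC, denominator zero
  expect_identical(margin_spicules(radial_sequence(rep(100, 64))), Inf)

  # single spectral line at w = pi/2 rides on a dominant DC term
  i <- 0:255
  r <- 100 + 3 * cos(64 * 2 * pi * i / 256)
  ms <- margin_spicules(radial_sequence(r))
  expect_equal(ms, oracle_spicules(r), tolerance = 1e-9)
  expect_equal(ms, 100 * 256 / (3 * 128), tolerance = 1e-6)

  # high-frequency perturbation strictly decreases the ratio
  for (s in 1:5) {
    set.seed(s)
    base <- 100 + 5 * cos(3 * 2 * pi * i / 256 + s)
    pert <- base + 2 * cos(100 * 2 * pi * i / 256)
    expect_lt(margin_spicules(radial_sequence(pert)),
              margin_spicules(radial_sequence(base)))
  }

  expect_error(margin_spicules(radial_sequence(rep(10, 4))), "at least 8")
})

test_that("margin spicules match the direct-summation DFT oracle", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(c(64, 128, 256, 512), 1)
    r <- 50 + stats::runif(1, 1, 10) * cos(sample(2:20, 1) * 2 * pi * (0:(n - 1)) / n) +
         stats::rnorm(n, 0, 0.5)
    r <- pmax(r, 1)
    expect_equal(margin_spicules(radial_sequence(r)), oracle_spicules(r),
                 tolerance = 1e-9)
  }
})

test_that("margin coarseness is the cyclic mean absolute difference", {
  expect_equal(margin_coarseness(list(r = rep(7, 16))), 0)
  expect_equal(margin_coarseness(list(r = c(10, 12, 10, 12))), 2)
  for (s in 1:200) {
    set.seed(s)
    r <- stats::runif(sample(8:200, 1), 5, 50)
    expect_equal(margin_coarseness(list(r = r)), oracle_coarseness(r),
                 tolerance = 1e-12)
  }
  expect_error(margin_coarseness(list(r = 3)), "short")
})

test_that("margin indistinctness sums Sobel magnitude over the boundary band", {
  # constant image: zero gradient everywhere
  sq <- cbind(c(20, 20, 44, 44), c(20, 44, 44, 20))
  roi <- lesion_roi(matrix(77, 64, 64), contour = sq)
  expect_equal(margin_indistinctness(roi), 0)

  # vertical step edge crossing the lesion: equals the brute-force band sum
  img <- matrix(0, 64, 64); img[, 33:64] <- 100
  roi2 <- lesion_roi(img, contour = cbind(c(20, 20, 44, 44), c(20, 44, 44, 20)))
  bw <- 5
  band <- matrix(FALSE, 64, 64)
  for (i in seq_len(nrow(roi2$boundary))) {
    for (dr in -bw:bw) for (dc in -bw:bw) {
      if (dr^2 + dc^2 > bw^2) next
      rr <- roi2$boundary[i, 1] + dr; cc <- roi2$boundary[i, 2] + dc
      if (rr >= 1 && rr <= 64 && cc >= 1 && cc <= 64) band[rr, cc] <- TRUE
    }
  }
  expect_equal(margin_indistinctness(roi2, bw),
               sum(oracle_sobel_magnitude(img)[band]), tolerance = 1e-9)
  # the step contributes 4*100 per band pixel on the two columns flanking it
  expect_equal(margin_indistinctness(roi2, bw),
               400 * sum(band[, 32:33]), tolerance = 1e-9)

  # blurring the margin strictly decreases the feature
  mis <- vapply(c(0, 1, 2, 4), function(s) {
    ph <- make_phantom(phantom_spec(canvas = c(96, 96), r0 = 25,
                                    margin_sigma = s, speckle_sigma = 0,
                                    seed = 9))
    margin_indistinctness(lesion_roi(ph$image, contour = ph$contour))
  }, numeric(1))
  expect_true(all(diff(mis) < 0))
})

test_that("margin lobulation counts planted harmonic extrema", {
  n <- 360
  th <- 2 * pi * (0:(n - 1)) / n
  expect_equal(margin_lobulation(radial_sequence(100 + 10 * cos(3 * th))), 6)
  expect_equal(margin_lobulation(radial_sequence(rep(100, n))), 0)
  expect_error(margin_lobulation(radial_sequence(rep(100, 20))), "too short")

  # noisy recovery of 2k extrema for k = 2..8 at boundary-trace sampling density
  n <- 720
  th <- 2 * pi * (0:(n - 1)) / n
  for (k in 2:8) {
    hits <- 0
    for (s in 1:20) {
      set.seed(1000 * k + s)
      r <- 100 * (1 + 0.1 * cos(k * th)) + stats::rnorm(n, 0, 0.5)
      if (margin_lobulation(radial_sequence(r)) == 2 * k) hits <- hits + 1
    }
    expect_gte(hits, 18)
  }
})

test_that("margin features are translation invariant", {
  base <- random_phantom_roi(13)$roi
  big <- matrix(FALSE, 160, 160)
  idx <- which(base$mask, arr.ind = TRUE)
  big[cbind(idx[, 1] + 9, idx[, 2] + 4)] <- TRUE
  img <- matrix(0, 160, 160)
  src <- dim(base$image)
  img[1:src[1] + 9, 1:src[2] + 4] <- base$image
  roi2 <- lesion_roi(img, mask = big)

  rs1 <- to_radial_sequence(base$boundary, base$centroid)
  rs2 <- to_radial_sequence(roi2$boundary, roi2$centroid)
  expect_equal(margin_coarseness(rs2), margin_coarseness(rs1), tolerance = 1e-9)
  expect_equal(margin_spicules(rs2), margin_spicules(rs1), tolerance = 1e-9)
  expect_equal(margin_lobulation(rs2), margin_lobulation(rs1))
  expect_equal(margin_indistinctness(roi2), margin_indistinctness(base),
               tolerance = 1e-9)
})
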