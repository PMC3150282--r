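test_that("preprocessing divides the flat field and subtracts background", {
  img <- matrix(100, 10, 10)
  expect_equal(preprocess(img, 1, 0), img, ignore_attr = TRUE)
  expect_equal(preprocess(img, 1, 30)[1, 1], 70)
  # an illumination gradient is removed to sub-percent flatness
  grad <- outer(seq(0.7, 1.3, length.out = 50), rep(1, 50))
  noisy <- 200 * grad
  corr <- preprocess(noisy, flat_field = grad, background = 0)
  expect_lt(stats::sd(corr) / mean(corr), 0.01)
  expect_warning(preprocess(matrix(1, 5, 5), 1, background = 2), "clipped")
  expect_error(preprocess(img, flat_field = 0), "positive")
})

test_that("Richardson-Lucy restores a blurred point source", {
  delta <- gaussian_psf(0, 3)
  img <- matrix(runif(400, 10, 50), 20, 20)
  expect_equal(richardson_lucy(img, delta, 5), img, tolerance = 1e-8)
  flat <- matrix(7, 20, 20)
  expect_equal(richardson_lucy(flat, gaussian_psf(1.5, 5), 10), flat,
               tolerance = 1e-6)
  # point source: forward blur then deconvolve recovers >= 80% of the peak
  ps <- matrix(0.1, 33, 33); ps[17, 17] <- 100
  psf <- gaussian_psf(1, 6)
  blurred <- conv2_replicate(ps, psf)
  expect_lt(max(blurred), 20)
  dec <- richardson_lucy(blurred, psf, 50)
  expect_gt(dec[17, 17], 0.8 * 100)
  expect_true(all(dec >= 0))
  expect_equal(sum(dec), sum(blurred), tolerance = 0.02)
  expect_warning(richardson_lucy(ps, psf * 2, 1), "normalis")
})

test_that("chromatic shift is recovered from constructed misalignment", {
  set.seed(11)
  ch1 <- gaussian_blur(matrix(rnorm(64^2), 64, 64), 2)
  ch2 <- sqrex:::shift_image(ch1, 1, 2)
  ch2[is.na(ch2)] <- 0
  res <- correct_chromatic_shift(ch1, ch2, max_shift_px = 3)
  expect_equal(res$shift, c(-1, -2))
  expect_gt(abs(res$correlation), 0.95)
  expect_equal(correct_chromatic_shift(ch1, ch1)$shift, c(0, 0))
  # anti-correlated channels still register via the correlation magnitude
  ch3 <- sqrex:::shift_image(-ch1 + 10, 2, 0); ch3[is.na(ch3)] <- 10
  res3 <- correct_chromatic_shift(ch1, ch3, max_shift_px = 3)
  expect_equal(res3$shift, c(-2, 0))
  expect_lt(res3$correlation, -0.9)
  expect_error(correct_chromatic_shift(ch1, matrix(1, 64, 64)), "variance")
})

test_that("contour tracking follows a synthetic annulus", {
  n <- 61; r0 <- 20
  d <- sqrt(outer((1:n - 31)^2, (1:n - 31)^2, `+`))
  ring <- 100 * exp(-(d - r0)^2 / 2) + 2
  tc <- track_contour(ring, seed_point = c(31 + r0, 31), threshold = 30)
  # closed 8-connected chain with length within 10% of the circumference
  dd <- abs(diff(rbind(tc$chain, tc$chain[1, ])))
  expect_lte(max(pmax(dd[, 1], dd[, 2])), 1)
  expect_equal(nrow(tc$chain), 2 * pi * r0, tolerance = 0.1)
  expect_equal(mean(tc$radius), r0, tolerance = 0.02)
  # orientation (counter-clockwise) independent of the seed point
  tc2 <- track_contour(ring, seed_point = c(31, 31 - r0), threshold = 30)
  area <- function(ch) {
    x <- ch[, 1] - mean(ch[, 1]); y <- ch[, 2] - mean(ch[, 2])
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }
  expect_gt(area(tc$chain), 0)
  expect_gt(area(tc2$chain), 0)
  # a broken ridge is reported with its gap location
  ring2 <- ring
  ring2[d > r0 - 2 & d < r0 + 2 & outer(1:n > 40, rep(TRUE, n))] <- 2
  expect_error(track_contour(ring2, c(31 + r0, 31), threshold = 30), "broken")
})

test_that("region extraction recovers the generator's membrane labels", {
  zs <- generate_zstack(seed = 2)
  masks <- extract_regions(zs$image, zs$truth$contours, max_offset = 3)
  expect_false(any(masks$free_surface & masks$contact_interface))
  # near-membrane truth voxels on the cap interior are assigned to the
  # right region (the cap rim itself is label-ambiguous by construction)
  tr <- zs$truth
  dm <- dim(tr$region)
  dz <- (slice.index(tr$region, 3) - tr$centre[3]) * tr$anisotropy
  r_inplane2 <- (slice.index(tr$region, 1) - tr$centre[1])^2 + dz^2
  cap_r <- sqrt(tr$radius_px^2 - (tr$plane_col - tr$centre[2])^2)
  core_ci <- tr$region == 2L & tr$dist_mem <= 1 &
    r_inplane2 <= (cap_r - 2)^2
  expect_gte(mean(masks$contact_interface[core_ci]), 0.95)
  # transect offsets are roughly symmetric about the contour
  expect_lt(abs(mean(masks$transects$offset)), 0.6)
  expect_error(extract_regions(zs$image, lapply(zs$truth$contours, function(co)
    if (is.null(co)) NULL else list(chain = co$chain)), 3), "annotations")
})

test_that("channel correlation behaves as Pearson on the mask", {
  x <- matrix(runif(100, 1, 5), 10, 10)
  img <- two_channel_image(x, x)
  m <- matrix(TRUE, 10, 10)
  expect_equal(channel_correlation(img, m), 1)
  img2 <- two_channel_image(x, max(x) - x)
  expect_equal(channel_correlation(img2, m), -1)
  expect_error(channel_correlation(two_channel_image(x, 0 * x), m), "variance")
})

test_that("component labelling honours the requested connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[5, 5] <- TRUE
  lab8 <- sqrex:::label_components(m, 8)
  expect_equal(max(lab8), 2)       # diagonal pair merges
  lab4 <- sqrex:::label_components(m, 4)
  expect_equal(max(lab4), 3)
})

test_that("TIFF round trip preserves counts and geometry", {
  b <- generate_bilayer(nrow = 24, ncol = 24, seed = 3)
  base <- file.path(tempdir(), "rt")
  write_two_channel_tiff(b$image, base)
  back <- read_two_channel_tiff(base)
  expect_equal(back$small, b$image$small, tolerance = 1e-6)
  expect_equal(back$long, b$image$long, tolerance = 1e-6)
  expect_equal(back$pixel_size_nm, 167)
  zs <- generate_zstack(nx = 32, ny = 32, nz = 5, radius_px = 10,
                        cap_depth_px = 4, seed = 1)
  base2 <- file.path(tempdir(), "rt3")
  write_two_channel_tiff(zs$image, base2)
  back2 <- read_two_channel_tiff(base2)
  expect_equal(back2$small, zs$image$small, tolerance = 1e-6)
  expect_equal(dim(back2$long), c(32, 32, 5))
})
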