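test_that("separation fields respect their construction", {
  sp <- spring_params()
  z_u <- sample_separation_field("uniform", sp, 16, 16, z_const = 15)
  expect_true(all(z_u == 15))
  for (s in 1:4) {
    z2 <- sample_separation_field("two_phase", sp, 64, 64, seed = s)
    expect_true(all(z2 >= sp$z_C - 1 & z2 <= sp$z_I + 1))
    zg <- sample_separation_field("smooth_grf", sp, 64, 64, seed = s)
    expect_true(all(zg >= sp$z_C & zg <= sp$z_I))
  }
  # two-phase histograms have exactly two density modes (fixed bandwidth)
  n_modes <- vapply(1:5, function(s) {
    z <- sample_separation_field("two_phase", sp, 64, 64, seed = s,
                                 wall_width = 0.4)
    d <- stats::density(z, bw = 0.5)
    pk <- which(diff(sign(diff(d$y))) == -2) + 1
    length(pk[d$y[pk] > 0.1 * max(d$y)])
  }, integer(1))
  expect_true(all(n_modes == 2))
  # determinism per seed
  expect_identical(sample_separation_field("two_phase", sp, 32, 32, seed = 9),
                   sample_separation_field("two_phase", sp, 32, 32, seed = 9))
})

test_that("the latent Gaussian field has the requested correlation structure", {
  g <- gaussian_random_field(256, 256, corr_len = 8, seed = 3)
  expect_equal(stats::sd(as.vector(g)), 1, tolerance = 0.1)
  expect_lt(abs(mean(g)), 0.15)
  # empirical lag-d correlation close to the squared-exponential model
  lag_cor <- function(d) stats::cor(as.vector(g[1:(256 - d), ]),
                                    as.vector(g[(1 + d):256, ]))
  expect_equal(lag_cor(4), exp(-16 / 128), tolerance = 0.1)
  expect_equal(lag_cor(8), exp(-64 / 128), tolerance = 0.12)
  expect_lt(lag_cor(40), 0.2)
})

test_that("bilayer generator draws counts from the exact model means", {
  b <- generate_bilayer(seed = 4)
  ci <- b$masks$contact_interface; fs <- b$masks$free_surface
  sp <- b$truth$spec
  # energies consistent with the separation field through the spring model
  expect_equal(b$truth$E_C, spring_energy(b$truth$z, b$truth$springs, "complex"))
  expect_equal(b$truth$e_C, sqrt(b$truth$E_C))
  # empirical fs mean within 3 SE of the model mean
  m_fs <- sp$mu_fs_small + sp$bg_small
  expect_lt(abs(mean(b$image$small[fs]) - m_fs), 3 * sqrt(m_fs / sum(fs)))
  # per-pixel ci means: standardised residuals ~ N(0,1)
  zres <- (b$image$small[ci] - ci_mean_small(sp, b$truth$e_C[ci])) /
    sqrt(ci_mean_small(sp, b$truth$e_C[ci]))
  expect_lt(abs(mean(zres)), 3 / sqrt(sum(ci)) * 1.5)
  expect_equal(stats::sd(zres), 1, tolerance = 0.06)
  # mutual exclusion visible as negative channel correlation
  expect_lt(channel_correlation(b$image, ci), -0.2)
  # determinism
  b2 <- generate_bilayer(seed = 4)
  expect_identical(b$image$small, b2$image$small)
})

test_that("no binding means ci and fs small-channel distributions agree", {
  sp <- fluor_spec(A_B = 0, Gamma_barrier = 1)
  b <- generate_bilayer(spec = sp, seed = 6)
  ks <- suppressWarnings(
    stats::ks.test(b$image$small[b$masks$contact_interface],
                   b$image$small[b$masks$free_surface]))
  expect_gt(ks$p.value, 0.01)
})

test_that("z-stack generator produces a trackable shell with exclusion on the cap", {
  zs <- generate_zstack(seed = 2)
  img <- zs$image
  expect_equal(dim(img$small), c(48, 48, 13))
  # mid-stack slice shows a closed ring the contour tracker follows
  k <- 7
  sl <- gaussian_blur(img$small[, , k] + img$long[, , k], 1)
  tc <- track_contour(sl, seed_point = zs$truth$contours[[k]]$chain[1, ],
                      threshold = stats::quantile(sl, 0.85))
  d <- abs(diff(rbind(tc$chain, tc$chain[1, ])))
  expect_lte(max(pmax(d[, 1], d[, 2])), 1)   # closed, 8-connected
  rk <- sqrt(zs$truth$radius_px^2 -
             ((k - zs$truth$centre[3]) * zs$truth$anisotropy)^2)
  expect_equal(mean(tc$radius), rk, tolerance = 0.12)
  # long ligand is excluded on the contact cap relative to the free surface
  masks <- extract_regions(img, zs$truth$contours, max_offset = 3)
  expect_lt(mean(img$long[masks$contact_interface]),
            0.7 * mean(img$long[masks$free_surface]))
  # Gamma noise leaves right-skewed per-region intensities
  sk <- function(x) mean(((x - mean(x)) / stats::sd(x))^3)
  expect_gt(sk(img$small[masks$free_surface]), 0)
  # geometry overflow is refused
  expect_error(generate_zstack(nx = 24, ny = 24, radius_px = 20), "margin")
})

test_that("step phantom blurs as specified", {
  sp <- fluor_spec(mu_fs_small = 160, mu_fs_long = 320, A_B = 800,
                   bg_small = 10, bg_long = 10)
  ph0 <- step_phantom_and_blur(spec = sp, psf_sigma = 0, noise = FALSE, seed = 1)
  expect_equal(ph0$image$small, ph0$truth$mean_small)
  ph <- step_phantom_and_blur(spec = sp, psf_sigma = 2, noise = FALSE, seed = 1)
  # wall width from an error-function fit of the blurred profile
  prof <- rev(ph$image$small[24, ])  # ascending across the wall
  lo <- min(ph$truth$mean_small); hi <- max(ph$truth$mean_small)
  pnl <- stats::nls((prof - lo) / (hi - lo) ~ pnorm(x, m, s),
                    data = list(x = seq_along(prof), prof = prof),
                    start = list(m = ncol(ph$image$small) / 2, s = 2))
  expect_equal(abs(coef(pnl)[["s"]]), 2, tolerance = 0.15)
})
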