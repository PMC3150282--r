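test_that("degenerate compositions give the expected single steady state", {
  # no long ligand: membranes settle at the bond length with complexes formed
  p <- dynamics_params(I_tot = 0)
  ss <- uniform_steady_states(p)
  expect_length(ss, 1)
  expect_equal(ss[[1]]$z_star, p$springs$z_C, tolerance = 1e-6)
  expect_gt(ss[[1]]$C, 0)
  # no receptor/ligand: long ligand relaxes the separation to its own length
  p2 <- dynamics_params(R_tot = 0, L_tot = 0)
  ss2 <- uniform_steady_states(p2)
  expect_length(ss2, 1)
  expect_equal(ss2[[1]]$z_star, p2$springs$z_I, tolerance = 1e-6)
  expect_equal(ss2[[1]]$C, 0)
})

test_that("a bistable composition has 3 states with an unstable middle", {
  p <- three_state_params()
  ss <- uniform_steady_states(p)
  expect_length(ss, 3)
  z <- vapply(ss, `[[`, numeric(1), "z_star")
  expect_true(all(diff(z) > 0))
  # extremes near the two natural lengths, both stable
  expect_lt(abs(z[1] - p$springs$z_C), 1)
  expect_lt(abs(z[3] - p$springs$z_I), 1.5)
  expect_true(ss[[1]]$stable_homog)
  expect_true(ss[[3]]$stable_homog)
  # the middle state is unstable to homogeneous AND spatial perturbations
  expect_false(ss[[2]]$stable_homog)
  expect_false(ss[[2]]$stable_spatial)
  J <- sqrex:::homogeneous_jacobian(ss[[2]], p)
  expect_gt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
  # oracle: dense force-balance scan sign changes equal the root count
  zs <- seq(p$springs$z_C - 5, p$springs$z_I + 5, length.out = 2000)
  g <- vapply(zs, sqrex:::force_balance_residual, numeric(1), p = p)
  expect_equal(sum(g[-1] * g[-length(g)] < 0), 3)
})

test_that("analytic margin sign matches the numerical dispersion relation", {
  set.seed(42)
  ks <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10)
  n_ok <- 0L; n_tot <- 0L
  for (i in 1:60) {
    sp <- spring_params(lambda_C = exp(runif(1, log(0.02), log(0.6))),
                        lambda_I = exp(runif(1, log(0.02), log(0.6))),
                        z_C = runif(1, 12, 14), z_I = 18)
    p <- dynamics_params(D_R = runif(1, 0.05, 1), D_L = runif(1, 0.05, 1),
                         D_C = runif(1, 0.02, 0.5), D_I = runif(1, 0.02, 0.5),
                         kon = exp(runif(1, log(0.01), log(1))),
                         koff0 = exp(runif(1, log(0.1), log(10))),
                         springs = sp, kappa = runif(1, 10, 50),
                         sigma = 10^runif(1, -5, -2),
                         R_tot = runif(1, 50, 1500), L_tot = runif(1, 50, 1500),
                         I_tot = runif(1, 50, 3000),
                         area_ratio = runif(1, 0.5, 4))
    for (s in suppressWarnings(uniform_steady_states(p))) {
      m <- instability_condition(s, p, k = 0)
      if (abs(m) < 1e-6) next
      gr <- max(dispersion_relation(s, p, ks))
      n_tot <- n_tot + 1L
      if ((m > 0) == (gr > 1e-9)) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.99)
  expect_gte(n_tot, 60)
})

test_that("margin decreases with wavenumber and vanishing springs are stable", {
  p <- patterned_params()
  s <- uniform_steady_states(p)[[1]]
  ks <- c(0, 2, 5, 10, 20, 50, 200, 500)
  m <- vapply(ks, function(k) instability_condition(s, p, k), numeric(1))
  expect_true(all(diff(m) <= 1e-12))
  # bending k^4 dominates eventually: large-k modes decay
  expect_gt(m[1], 0)
  expect_lt(m[length(ks)], 0)
  expect_lt(dispersion_relation(s, p, 1e4), 0)
  # (near-)vanishing spring constants decouple the membrane: stable
  sp0 <- spring_params(lambda_C = 1e-8, lambda_I = 1e-8)
  p0 <- dynamics_params(springs = sp0)
  s0 <- uniform_steady_states(p0)[[1]]
  expect_lt(instability_condition(s0, p0, 0), 0)
  expect_lt(max(dispersion_relation(s0, p0, c(0.1, 1, 10))), 1e-9)
})

test_that("stability curve is the margin zero-set and depends only on the spring ratio", {
  p <- patterned_params()
  ln <- sqre_line(1.6, 0.7)
  sc <- stability_curve(ln, p, e_max = 3, n = 41)
  expect_gt(nrow(sc$curve), 5)
  for (i in seq_len(min(10, nrow(sc$curve)))) {
    st <- sqrex:::state_at_sqre(sc$curve$e_C[i], sc$curve$e_I[i], p)
    m <- sqrex:::sqre_margin(sc$curve$e_C[i], sc$curve$e_I[i],
                             st$R, st$L, st$C, st$I, p, k = 0)
    expect_lt(abs(m), 1e-6)
  }
  # joint rescaling of both spring constants leaves the curve unchanged
  p2 <- patterned_params()
  p2$springs <- spring_params(lambda_C = 3 * p$springs$lambda_C,
                              lambda_I = 3 * p$springs$lambda_I)
  sc2 <- stability_curve(ln, p2, e_max = 3, n = 41)
  expect_equal(sc2$margin, sc$margin, tolerance = 1e-8)
  # absolute softness is irrelevant at k = 0 (only the ratio matters), but
  # the elastic penalty breaks the invariance at finite wavenumber: a
  # thousandfold softer pair of springs is stabilised at wavenumbers the
  # stiff pair still leaves unstable
  s_stiff <- uniform_steady_states(p)[[1]]
  p5 <- patterned_params()
  p5$springs <- spring_params(lambda_C = p$springs$lambda_C / 1000,
                              lambda_I = p$springs$lambda_I / 1000)
  s_soft <- uniform_steady_states(p5)[[1]]
  k_probe <- 5
  expect_gt(instability_condition(s_stiff, p, k_probe),
            instability_condition(s_soft, p5, k_probe))
})

test_that("patternation test finds the unstable segment away from the endpoints", {
  p <- patterned_params()
  ln <- sqre_line(1.6, 0.7)
  pt <- patternation_test(ln, p)
  expect_true(pt$intersects)
  # pure-species endpoints are outside the unstable segment
  expect_gt(pt$unstable_segment[1], 0)
  expect_lt(pt$unstable_segment[2], ln$alpha / ln$beta)
  expect_lt(pt$margin[1], 0)
  expect_lt(pt$margin[length(pt$margin)], 0)
  # a nearly degenerate line sits entirely in the stable region
  pt0 <- patternation_test(sqre_line(0.05, 0.7), p)
  expect_false(pt0$intersects)
})

test_that("patch statistics match the normal-tail closed form and self-consistency", {
  st <- close_contact_patch_stats(mean_sep = 18, sd_sep = 3, corr_len = 20,
                                  threshold = 12, domain_nm = 2000,
                                  grid_nm = 5, n_rep = 6, seed = 2)
  expect_equal(st$area_fraction_closed_form, pnorm(-2))
  expect_lt(abs(st$area_fraction - pnorm(-2)), 3 * st$area_fraction_se)
  # density x mean patch area ~ area fraction
  expect_equal(st$patch_density_um2 * st$mean_patch_area_nm2 * 1e-6,
               st$area_fraction, tolerance = 0.1)
  # threshold far above the mean captures everything
  st2 <- close_contact_patch_stats(threshold = 60, domain_nm = 500, n_rep = 2,
                                   seed = 1)
  expect_equal(st2$area_fraction, 1)
})

test_that("2D dissociation constant follows mass action", {
  expect_equal(kd_2d_from_enrichment(100, 50, 190)$Kd_um2, 95)
  expect_equal(kd_2d_from_enrichment(190, 190, 190)$Kd_um2, 190)
  expect_equal(kd_2d_from_enrichment(200, 50, 190)$Kd_um2,
               kd_2d_from_enrichment(100, 50, 190)$Kd_um2 / 2)
  expect_error(kd_2d_from_enrichment(0, 50, 190), "positive")
  # brute-force equilibrium oracle: relax the binding ODE to steady state
  kon <- 0.05; koff <- 2
  R0 <- 190; L0 <- 120
  C <- 0; R <- R0; L <- L0
  for (i in 1:20000) {
    dC <- kon * R * L - koff * C
    C <- C + 0.002 * dC; R <- R0 - C; L <- L0 - C
  }
  Kd_true <- koff / kon
  est <- kd_2d_from_enrichment(B_opt = C, L_fs = L, R_density = R)
  expect_equal(est$Kd_um2, Kd_true, tolerance = 0.01)
})
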