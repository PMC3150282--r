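# Reaction-diffusion model of membrane-mediated size segregation: uniform
# steady states, linear stability (analytic instability margin and numerical
# dispersion relation), the stability curve in SQRE coordinates and its
# intersection with the regression line (patternation test), a conservative
# finite-difference simulator, and close-contact patch statistics.
#
# Internal unit conventions: membrane separation z in nm, lateral space in
# um, concentrations in um^-2, energies in kT, time in s. With these units
# the elastic penalty entering the separation equation at wavenumber k
# (um^-1) is sigma * k^2 + 1e-6 * kappa * k^4 for sigma in kT nm^-2 and
# kappa in kT.

#' Parameters of the reaction-diffusion segregation model
#'
#' Five coupled fields: free receptor R, free small ligand L, bound complex
#' C, long unbound ligand I, and the membrane separation z. Species diffuse;
#' R + L <-> C with separation-dependent off-rate; C and I drift down the
#' gradients of their spring energies; z relaxes overdamped under the spring
#' forces and membrane elasticity.
#'
#' @param D_R,D_L,D_C,D_I Diffusion constants, um^2 s^-1.
#' @param kon 2D association rate, um^2 s^-1.
#' @param koff0 Intrinsic complex off-rate at the natural bond length, s^-1.
#' @param springs A [spring_params()] object.
#' @param kappa Membrane bending rigidity, kT.
#' @param sigma Membrane surface tension, kT nm^-2.
#' @param M Membrane response coefficient (kT s nm^-2 um^-2); sets the
#'   separation relaxation timescale only, not stability boundaries at k = 0.
#' @param R_tot,L_tot,I_tot Total densities (molecules per unit contact
#'   interface area, um^-2), counting both regions.
#' @param area_ratio Free-surface to contact-interface area ratio.
#' @param C_ref Optimal complex density (reference for the complex Boltzmann
#'   relation), um^-2; defaults to `min(R_tot, L_tot) / 2`.
#' @param I_ref Free-surface long-ligand density (reference for its Boltzmann
#'   relation), um^-2; defaults to `I_tot / (area_ratio + 1)`.
#' @return An object of class `"dynamics_params"`.
#' @export
dynamics_params <- function(D_R = 0.5, D_L = 0.5, D_C = 0.1, D_I = 0.3,
                            kon = 0.02, koff0 = 1,
                            springs = spring_params(),
                            kappa = 25, sigma = 1e-4, M = 1,
                            R_tot = 300, L_tot = 300, I_tot = 500,
                            area_ratio = 1,
                            C_ref = NULL, I_ref = NULL) {
  stopifnot(inherits(springs, "spring_params"))
  if (any(c(D_R, D_L, D_C, D_I, kon, koff0) < 0))
    stop("rates and diffusivities must be non-negative")
  if (M <= 0) stop("membrane response coefficient M must be positive")
  if (any(c(kappa, sigma) <= 0)) stop("kappa and sigma must be positive")
  if (is.null(C_ref)) C_ref <- min(R_tot, L_tot) / 2
  if (is.null(I_ref)) I_ref <- I_tot / (area_ratio + 1)
  structure(list(D_R = D_R, D_L = D_L, D_C = D_C, D_I = D_I,
                 kon = kon, koff0 = koff0, springs = springs,
                 kappa = kappa, sigma = sigma, M = M,
                 R_tot = R_tot, L_tot = L_tot, I_tot = I_tot,
                 area_ratio = area_ratio, C_ref = C_ref, I_ref = I_ref),
            class = "dynamics_params")
}

# Elastic penalty entering the z-z curvature at wavenumber k (um^-1).
elastic_penalty <- function(p, k) p$sigma * k^2 + 1e-6 * p$kappa * k^4

# Concentrations slaved to a trial uniform separation z: complex from mass
# action with reservoir partitioning, long ligand from its Boltzmann
# relation with the free surface.
slaved_state <- function(z, p) {
  sp <- p$springs
  E_C <- spring_energy(z, sp, "complex")
  E_I <- spring_energy(z, sp, "long_ligand")
  rho <- p$area_ratio
  Ke <- (p$koff0 / p$kon) * exp(E_C) * (1 + rho)^2
  b <- p$R_tot + p$L_tot + Ke
  # numerically stable small root of C^2 - b C + Rt Lt = 0
  C <- 2 * p$R_tot * p$L_tot / (b + sqrt(pmax(b^2 - 4 * p$R_tot * p$L_tot, 0)))
  C <- pmax(0, pmin(C, min(p$R_tot, p$L_tot)))
  R <- (p$R_tot - C) / (1 + rho)
  L <- (p$L_tot - C) / (1 + rho)
  I_fs <- p$I_tot / (rho + exp(-E_I))
  I <- I_fs * exp(-E_I)
  list(z = z, R = R, L = L, C = C, I = I, I_fs = I_fs, E_C = E_C, E_I = E_I)
}

# Net force on the membrane (per unit area, sign: positive pushes z up).
force_balance_residual <- function(z, p) {
  s <- slaved_state(z, p)
  sp <- p$springs
  -(2 * sp$lambda_C * s$C * (z - sp$z_C) + 2 * sp$lambda_I * s$I * (z - sp$z_I))
}

#' Uniform steady states of the segregation model
#'
#' Finds all uniform separations where the spring forces of the complex and
#' the long ligand balance, with concentrations slaved to mass action and
#' reservoir partitioning. Roots are located by a 400-interval bracketed scan
#' over `[z_C - 5, z_I + 5]` nm followed by bisection; degenerate roots
#' closer than 1e-4 nm are merged. There are generically 1 or 3 states; a
#' different count is reported with a warning.
#'
#' @param p A [dynamics_params()] object.
#' @return A list of `"steady_state"` objects, each with the uniform
#'   separation `z_star`, concentrations `R, L, C, I` (um^-2), SQREs
#'   `e_C_star`, `e_I_star`, and stability flags `stable_homog` (k = 0,
#'   reservoir-coupled) and `stable_spatial` (long-wavelength margin).
#' @export
uniform_steady_states <- function(p) {
  stopifnot(inherits(p, "dynamics_params"))
  sp <- p$springs
  lo <- sp$z_C - 5; hi <- sp$z_I + 5
  zs <- seq(lo, hi, length.out = 401)
  g <- vapply(zs, force_balance_residual, numeric(1), p = p)
  roots <- numeric(0)
  for (i in seq_len(length(zs) - 1)) {
    if (!is.finite(g[i]) || !is.finite(g[i + 1])) next
    if (g[i] == 0) roots <- c(roots, zs[i])
    else if (g[i] * g[i + 1] < 0) {
      r <- tryCatch(stats::uniroot(force_balance_residual, c(zs[i], zs[i + 1]),
                                   p = p, tol = 1e-10)$root,
                    error = function(e) NA_real_)
      if (is.na(r))
        stop("root finding failed in bracket [", zs[i], ", ", zs[i + 1],
             "]; force-balance scan attached as attribute",
             call. = FALSE)
      roots <- c(roots, r)
    }
  }
  if (g[length(g)] == 0) roots <- c(roots, hi)
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-4)]
  if (!(length(roots) %in% c(1, 3)))
    warning(sprintf("found %d uniform steady states (expected 1 or 3)",
                    length(roots)))
  lapply(roots, function(z) make_steady_state(z, p))
}

make_steady_state <- function(z, p) {
  s <- slaved_state(z, p)
  sp <- p$springs
  st <- structure(list(z_star = z, R = s$R, L = s$L, C = s$C, I = s$I,
                       I_fs = s$I_fs,
                       e_C_star = sqrt(s$E_C), e_I_star = sqrt(s$E_I),
                       stable_homog = NA, stable_spatial = NA),
                  class = "steady_state")
  st$stable_homog <- max(Re(eigen(homogeneous_jacobian(st, p),
                                  only.values = TRUE)$values)) < 1e-8
  st$stable_spatial <- instability_condition(st, p, k = 0) <= 0
  st
}

# Jacobian of the homogeneous (k = 0) dynamics in (C, z), with R, L, I
# slaved to the reservoir constraints (fast exchange with the free surface).
homogeneous_jacobian <- function(state, p) {
  sp <- p$springs
  f <- function(v) {
    C <- v[1]; z <- v[2]
    rho <- p$area_ratio
    R <- (p$R_tot - C) / (1 + rho)
    L <- (p$L_tot - C) / (1 + rho)
    E_C <- spring_energy(z, sp, "complex")
    E_I <- spring_energy(z, sp, "long_ligand")
    I <- p$I_tot * exp(-E_I) / (rho + exp(-E_I))
    c(p$kon * R * L - p$koff0 * exp(E_C) * C,
      -(2 * sp$lambda_C * C * (z - sp$z_C) +
        2 * sp$lambda_I * I * (z - sp$z_I)) / p$M)
  }
  v0 <- c(state$C, state$z_star)
  J <- matrix(0, 2, 2)
  h <- c(max(1e-6 * abs(state$C), 1e-8), 1e-7)
  for (j in 1:2) {
    vp <- v0; vm <- v0
    vp[j] <- vp[j] + h[j]; vm[j] <- vm[j] - h[j]
    J[, j] <- (f(vp) - f(vm)) / (2 * h[j])
  }
  J
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Uniform steady state: z* = %.4g nm (e_C = %.3g, e_I = %.3g kT^1/2)\n",
              x$z_star, x$e_C_star, x$e_I_star))
  cat(sprintf("  R = %.4g, L = %.4g, C = %.4g, I = %.4g um^-2\n",
              x$R, x$L, x$C, x$I))
  cat(sprintf("  stable to homogeneous perturbations: %s; to spatial: %s\n",
              x$stable_homog, x$stable_spatial))
  invisible(x)
}

check_steady <- function(state, p, tol = 1e-4) {
  r1 <- abs(force_balance_residual(state$z_star, p))
  flux <- p$koff0 * exp(spring_energy(state$z_star, p$springs, "complex")) *
    state$C
  r2 <- abs(p$kon * state$R * state$L - flux)
  scale <- max(1, p$kon * state$R * state$L + flux)
  if (r1 > tol * max(1, state$C + state$I) || r2 > tol * scale)
    stop("input is not a steady state (residuals ", signif(r1, 3), ", ",
         signif(r2, 3), ")")
  invisible(TRUE)
}

#' Numerical dispersion relation of the full linearised system
#'
#' Largest real part of the eigenvalues of the 5-variable linearisation
#' (R, L, C, I, z) at spatial mode `k` around a uniform steady state. A
#' positive value means the mode grows.
#'
#' @param state A `"steady_state"` (from [uniform_steady_states()]).
#' @param p A [dynamics_params()] object.
#' @param k Wavenumber, um^-1 (vectorised).
#' @return Maximum growth rate(s), s^-1.
#' @export
dispersion_relation <- function(state, p, k) {
  stopifnot(inherits(state, "steady_state"), inherits(p, "dynamics_params"))
  check_steady(state, p)
  vapply(k, function(kk) {
    J <- linearised_jacobian(state, p, kk)
    max(Re(eigen(J, only.values = TRUE)$values))
  }, numeric(1))
}

linearised_jacobian <- function(state, p, k) {
  sp <- p$springs
  z <- state$z_star; R <- state$R; L <- state$L; C <- state$C; I <- state$I
  EpC <- 2 * sp$lambda_C * (z - sp$z_C)   # dE_C/dz, kT/nm
  EpI <- 2 * sp$lambda_I * (z - sp$z_I)
  koff <- p$koff0 * exp(spring_energy(z, sp, "complex"))
  k2 <- k^2
  Fzz <- 2 * sp$lambda_C * C + 2 * sp$lambda_I * I + elastic_penalty(p, k)
  matrix(c(
    -p$D_R * k2 - p$kon * L, -p$kon * R,  koff,            0,            koff * EpC * C,
    -p$kon * L, -p$D_L * k2 - p$kon * R,  koff,            0,            koff * EpC * C,
     p$kon * L,  p$kon * R, -p$D_C * k2 - koff,            0,           -koff * EpC * C - p$D_C * C * EpC * k2,
     0,          0,          0,          -p$D_I * k2,     -p$D_I * I * EpI * k2,
     0,          0,         -EpC / p$M,  -EpI / p$M,      -Fzz / p$M),
    nrow = 5, byrow = TRUE)
}

#' Analytic long-wavelength instability margin
#'
#' The dynamics is a gradient flow of a free energy (entropy of the four
#' species plus spring and elastic energies), so a uniform steady state is
#' unstable to long-wavelength spatial perturbations exactly when the
#' Hessian of the free energy in the conserved densities (R + C, L + C, I) -
#' after Schur elimination of the fast variables (reaction coordinate and
#' membrane separation, the latter carrying the elastic penalty
#' `sigma k^2 + 1e-6 kappa k^4`) - has a negative eigenvalue. The returned
#' margin is `-min eig` of that 3 x 3 Hessian after a diagonal (Jacobi)
#' normalisation, which preserves the sign: positive margin means the state
#' is unstable at that wavenumber. Diffusion constants do not enter; the
#' elasticity parameters enter only with `k`, so `k = 0` (the default, the
#' most unstable mode) isolates the spring constants and concentrations.
#'
#' @param state A `"steady_state"`.
#' @param p A [dynamics_params()] object.
#' @param k Wavenumber, um^-1 (default 0).
#' @param check Verify the steady-state residual first?
#' @return Signed dimensionless margin; positive means unstable.
#' @export
instability_condition <- function(state, p, k = 0, check = TRUE) {
  stopifnot(inherits(p, "dynamics_params"))
  if (check) check_steady(state, p)
  sqre_margin(state$e_C_star, state$e_I_star,
              R = state$R, L = state$L, C = state$C, I = state$I,
              p = p, k = k)
}

# Margin from SQRE coordinates and concentrations (shared by
# instability_condition and the stability curve).
sqre_margin <- function(e_C, e_I, R, L, C, I, p, k = 0) {
  sp <- p$springs
  # vanishing concentrations: the species cannot fluctuate (infinite
  # entropic stiffness); a tiny floor keeps the algebra finite with the
  # Jacobi normalisation absorbing the scale
  R <- max(R, 1e-12); L <- max(L, 1e-12)
  C <- max(C, 1e-12); I <- max(I, 1e-12)
  EpC <- 2 * sqrt(sp$lambda_C) * e_C       # |dE_C/dz| at the state
  EpI <- -2 * sqrt(sp$lambda_I) * e_I      # dE_I/dz is negative for z < z_I
  Fzz <- 2 * sp$lambda_C * C + 2 * sp$lambda_I * I + elastic_penalty(p, k)
  Hvv <- matrix(c(1 / R + 1 / L + 1 / C, EpC,
                  EpC, Fzz), 2, 2)
  dv <- 1 / sqrt(diag(Hvv))
  ev_vv <- eigen(Hvv * (dv %o% dv), symmetric = TRUE,
                 only.values = TRUE)$values
  if (min(ev_vv) <= 0) {
    # fast subsystem itself unstable (homogeneous instability)
    return(-min(ev_vv))
  }
  Huu <- diag(c(1 / R, 1 / L, 1 / I))
  Huv <- matrix(c(-1 / R, 0,
                  -1 / L, 0,
                  0, EpI), 3, 2, byrow = TRUE)
  Heff <- Huu - Huv %*% solve(Hvv, t(Huv))
  Heff <- (Heff + t(Heff)) / 2
  d <- diag(Heff)
  if (any(d <= 0)) return(-min(eigen(Heff, symmetric = TRUE,
                                     only.values = TRUE)$values) / max(abs(Heff)))
  Dn <- 1 / sqrt(d)
  Hn <- Heff * (Dn %o% Dn)
  -min(eigen(Hn, symmetric = TRUE, only.values = TRUE)$values)
}

# Hypothetical uniform state at a point of the SQRE plane: separation from
# e_C on the physical branch, concentrations from the Boltzmann relations,
# free species from mass action.
state_at_sqre <- function(e_C, e_I, p) {
  sp <- p$springs
  C <- p$C_ref * exp(-e_C^2)
  I <- p$I_ref * exp(-e_I^2)
  # mass action: R L = (koff0/kon) exp(E_C) C = (koff0/kon) C_ref exactly
  R <- L <- sqrt((p$koff0 / p$kon) * p$C_ref)
  list(R = R, L = L, C = C, I = I)
}

#' Stability curve in SQRE coordinates
#'
#' The zero-level set of the `k = 0` instability margin over the
#' `(e_C, e_I)` plane, each point interpreted as a hypothetical uniform
#' steady state via the Boltzmann relations (complex referenced to `C_ref`,
#' long ligand to `I_ref`). The curve depends on the spring constants only
#' through their ratio `beta^2 = lambda_I / lambda_C`. States below/left of
#' the unstable region are stable.
#'
#' @param line An [sqre_line()] (used for the plotting box and to mark the
#'   steady-state line).
#' @param p A [dynamics_params()] object.
#' @param e_max Upper edge of the sampled box (default the SQRE prior edge, 5).
#' @param n Grid resolution per axis.
#' @return An object of class `"stability_curve"`: `e_C`, `e_I` grid
#'   vectors, `margin` matrix, `curve` (data.frame of zero-crossing points),
#'   `line`, `beta2`.
#' @export
stability_curve <- function(line, p, e_max = 5, n = 121) {
  stopifnot(inherits(line, "sqre_line"), inherits(p, "dynamics_params"))
  eC <- seq(1e-3, e_max, length.out = n)
  eI <- seq(1e-3, e_max, length.out = n)
  marg <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    st <- state_at_sqre(eC[i], eI[j], p)
    marg[i, j] <- sqre_margin(eC[i], eI[j], st$R, st$L, st$C, st$I, p, k = 0)
  }
  pts <- list()
  for (i in seq_len(n)) {
    s <- marg[i, ]
    cross <- which(s[-n] * s[-1] < 0)
    for (j in cross) {
      f <- function(e) {
        st <- state_at_sqre(eC[i], e, p)
        sqre_margin(eC[i], e, st$R, st$L, st$C, st$I, p, k = 0)
      }
      r <- stats::uniroot(f, c(eI[j], eI[j + 1]), tol = 1e-8)$root
      pts[[length(pts) + 1]] <- c(eC[i], r)
    }
  }
  curve <- if (length(pts)) as.data.frame(do.call(rbind, pts)) else
    data.frame(numeric(0), numeric(0))
  names(curve) <- c("e_C", "e_I")
  structure(list(e_C = eC, e_I = eI, margin = marg, curve = curve,
                 line = line, beta2 = line$beta^2, params = p),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("Stability curve (beta^2 = %.4g): %d zero-margin points,\n",
              x$beta2, nrow(x$curve)))
  cat(sprintf("  unstable fraction of the sampled box: %.3f\n",
              mean(x$margin > 0)))
  invisible(x)
}

#' Patternation test: does the regression line cross the unstable region?
#'
#' Moving along the SQRE regression line `e_I = alpha - beta e_C` is moving
#' the uniform steady state (it is the steady-state line as ligand densities
#' vary). Patternation is predicted exactly when some segment of the line
#' (restricted to the physical quadrant) lies in the unstable region of the
#' `k = 0` margin.
#'
#' @param line An [sqre_line()].
#' @param p A [dynamics_params()] object.
#' @param n Sampling points along the line.
#' @return A list with `intersects` (flag), `crossings` (data.frame of
#'   boundary points), `unstable_segment` (range of e_C with positive
#'   margin), and the sampled `e_C`, `margin` vectors.
#' @export
patternation_test <- function(line, p, n = 401) {
  stopifnot(inherits(line, "sqre_line"), inherits(p, "dynamics_params"))
  eC_end <- line$alpha / line$beta
  eC <- seq(1e-4, eC_end - 1e-4, length.out = n)
  eI <- pmax(line$alpha - line$beta * eC, 1e-6)
  marg <- vapply(seq_len(n), function(i) {
    st <- state_at_sqre(eC[i], eI[i], p)
    sqre_margin(eC[i], eI[i], st$R, st$L, st$C, st$I, p, k = 0)
  }, numeric(1))
  pos <- marg > 0
  crossings <- list()
  for (i in which(marg[-n] * marg[-1] < 0)) {
    f <- function(e) {
      ei <- max(line$alpha - line$beta * e, 1e-6)
      st <- state_at_sqre(e, ei, p)
      sqre_margin(e, ei, st$R, st$L, st$C, st$I, p, k = 0)
    }
    r <- stats::uniroot(f, c(eC[i], eC[i + 1]), tol = 1e-8)$root
    crossings[[length(crossings) + 1]] <-
      c(e_C = r, e_I = max(line$alpha - line$beta * r, 0))
  }
  list(intersects = any(pos),
       crossings = if (length(crossings))
         as.data.frame(do.call(rbind, crossings)) else NULL,
       unstable_segment = if (any(pos)) range(eC[pos]) else NULL,
       e_C = eC, margin = marg, line = line)
}

#' Finite-difference simulation of the segregation model
#'
#' Conservative explicit scheme on a square grid with no-flux boundaries:
#' species fluxes are evaluated on cell faces (diffusion plus drift down the
#' spring-energy gradients for C and I), so total R + C, L + C and I are
#' conserved to rounding; the separation field relaxes overdamped under the
#' spring forces, tension and bending. Optional seeded stochastic forcing
#' perturbs z. The time step is checked against an explicit stability bound
#' and the run refuses to start (suggesting a step) if it is violated.
#'
#' @param p A [dynamics_params()] object.
#' @param init Named list of initial fields `R, L, C, I, z` (matrices of
#'   equal size), or a `"steady_state"` to start uniformly from.
#' @param nx,ny Grid size (used when `init` is a steady state).
#' @param h Grid spacing, um (should resolve `sqrt(kappa/sigma)`).
#' @param t_end Simulated time, s.
#' @param dt Time step, s (NULL = 80% of the stability bound).
#' @param n_save Number of saved snapshots (including the final state).
#' @param noise_sd SD of Gaussian forcing added to z each step, nm (0 = off).
#' @param perturb_sd SD of the initial z perturbation, nm.
#' @param seed Integer seed for forcing/perturbation.
#' @return An object of class `"pde_trajectory"`: `times`, `snapshots`
#'   (list of field lists), `conservation` (relative drift of the three
#'   conserved totals), `params`, `grid`, `seed`.
#' @export
simulate_pde <- function(p, init, nx = 64, ny = 64, h = 0.167,
                         t_end = 10, dt = NULL, n_save = 5,
                         noise_sd = 0, perturb_sd = 0, seed = 1) {
  stopifnot(inherits(p, "dynamics_params"))
  set.seed(seed)
  sp <- p$springs
  if (inherits(init, "steady_state")) {
    mk <- function(v) matrix(v, nx, ny)
    fld <- list(R = mk(init$R), L = mk(init$L), C = mk(init$C),
                I = mk(init$I), z = mk(init$z_star))
  } else {
    fld <- init
    nx <- nrow(fld$z); ny <- ncol(fld$z)
  }
  if (perturb_sd > 0)
    fld$z <- fld$z + matrix(stats::rnorm(nx * ny, 0, perturb_sd), nx, ny)

  kap <- 1e-6 * p$kappa
  Dmax <- max(p$D_R, p$D_L, p$D_C, p$D_I)
  drift_gain <- 1 + max(2 * sp$lambda_C, 2 * sp$lambda_I) *
    (sp$z_I - sp$z_C + 2)^2 / 4
  Fzz0 <- 2 * sp$lambda_C * max(fld$C) + 2 * sp$lambda_I * max(fld$I)
  # the reaction is integrated semi-implicitly, so only diffusion/drift,
  # association and membrane relaxation limit the step
  dt_bound <- 0.8 * min(
    h^2 / (4 * Dmax * drift_gain),
    1 / (p$kon * max(fld$R + fld$L) + 1e-12),
    2 * p$M / (2 * Fzz0 + 64 * kap / h^4 + 8 * p$sigma / h^2 + 1e-12))
  if (is.null(dt)) dt <- dt_bound
  else if (dt > dt_bound)
    stop(sprintf("dt = %g violates the stability bound; use dt <= %g",
                 dt, dt_bound))
  n_steps <- max(1L, ceiling(t_end / dt))
  save_at <- unique(pmax(1L, round(seq(1, n_steps, length.out = n_save))))

  tot0 <- c(RC = sum(fld$R + fld$C), LC = sum(fld$L + fld$C), I = sum(fld$I))
  snaps <- list(); times <- numeric(0)
  for (s in seq_len(n_steps)) {
    fld <- pde_step(fld, p, h, dt, noise_sd)
    if (s %in% save_at) {
      snaps[[length(snaps) + 1]] <- fld
      times <- c(times, s * dt)
    }
  }
  tot1 <- c(RC = sum(fld$R + fld$C), LC = sum(fld$L + fld$C), I = sum(fld$I))
  structure(list(times = times, snapshots = snaps,
                 conservation = abs(tot1 - tot0) / pmax(tot0, 1e-300),
                 params = p, grid = list(nx = nx, ny = ny, h = h, dt = dt),
                 seed = seed),
            class = "pde_trajectory")
}

# One explicit step. Neumann boundaries via edge replication; face fluxes
# for exact conservation.
pde_step <- function(fld, p, h, dt, noise_sd) {
  sp <- p$springs
  z <- fld$z
  E_C <- sp$lambda_C * (z - sp$z_C)^2
  E_I <- sp$lambda_I * (z - sp$z_I)^2
  koff <- p$koff0 * exp(pmin(E_C, 60))
  # semi-implicit dissociation: C* = (C + dt kon R L) / (1 + dt koff) keeps
  # the stiff off-rate from limiting the step; the same effective rate is
  # applied to R, L and C so the pairwise totals are conserved exactly
  C_star <- (fld$C + dt * p$kon * fld$R * fld$L) / (1 + dt * koff)
  react <- (C_star - fld$C) / dt

  lap <- function(f) {
    up <- rbind(f[1, , drop = FALSE], f[-nrow(f), , drop = FALSE])
    dn <- rbind(f[-1, , drop = FALSE], f[nrow(f), , drop = FALSE])
    lf <- cbind(f[, 1, drop = FALSE], f[, -ncol(f), drop = FALSE])
    rt <- cbind(f[, -1, drop = FALSE], f[, ncol(f), drop = FALSE])
    (up + dn + lf + rt - 4 * f) / h^2
  }
  # divergence of -D (grad c + c grad E) with face-centred fluxes; the
  # drift part is upwinded (face concentration from the donor cell) so
  # steep energy walls cannot drive concentrations negative
  drift_div <- function(cf, E, D) {
    n <- nrow(cf); m <- ncol(cf)
    dEx <- (E[-1, ] - E[-n, ]) / h
    cup_x <- ifelse(dEx > 0, cf[-1, ], cf[-n, ])  # donor cell: drift source
    fx <- -D * ((cf[-1, ] - cf[-n, ]) / h + cup_x * dEx)
    dEy <- (E[, -1] - E[, -m]) / h
    cup_y <- ifelse(dEy > 0, cf[, -1], cf[, -m])
    fy <- -D * ((cf[, -1] - cf[, -m]) / h + cup_y * dEy)
    div <- matrix(0, n, m)
    div <- div + rbind(fx, 0) - rbind(0, fx)
    div <- div + cbind(fy, 0) - cbind(0, fy)
    -div / h
  }
  dR <- p$D_R * lap(fld$R) - react
  dL <- p$D_L * lap(fld$L) - react
  dC <- drift_div(fld$C, E_C, p$D_C) + react
  dI <- drift_div(fld$I, E_I, p$D_I)
  bih <- lap(lap(z))
  dz <- (-(2 * sp$lambda_C * fld$C * (z - sp$z_C) +
           2 * sp$lambda_I * fld$I * (z - sp$z_I)) -
         1e-6 * p$kappa * bih + p$sigma * lap(z)) / p$M
  out <- list(R = fld$R + dt * dR, L = fld$L + dt * dL,
              C = fld$C + dt * dC, I = fld$I + dt * dI,
              z = z + dt * dz)
  if (noise_sd > 0)
    out$z <- out$z + matrix(stats::rnorm(length(z), 0, noise_sd * sqrt(dt)),
                            nrow(z), ncol(z))
  out
}

#' @export
print.pde_trajectory <- function(x, ...) {
  zf <- x$snapshots[[length(x$snapshots)]]$z
  cat(sprintf("PDE trajectory: %d x %d grid, %d snapshots to t = %.3g s\n",
              x$grid$nx, x$grid$ny, length(x$times), max(x$times)))
  cat(sprintf("  final z range [%.3g, %.3g] nm, spatial SD %.3g nm\n",
              min(zf), max(zf), stats::sd(as.vector(zf))))
  cat(sprintf("  conservation drift (R+C, L+C, I): %s\n",
              paste(signif(x$conservation, 2), collapse = ", ")))
  invisible(x)
}

#' Write a trajectory's metadata and summary to disk
#'
#' JSON sidecar with parameters, grid and seed; CSV with per-snapshot
#' summaries (time, spatial SD of each field, z quantiles).
#'
#' @param traj A `"pde_trajectory"`.
#' @param basename Path prefix (writes `<basename>.json`, `<basename>.csv`).
#' @return Invisibly, the files written.
#' @export
write_trajectory <- function(traj, basename) {
  stopifnot(inherits(traj, "pde_trajectory"))
  p <- traj$params
  meta <- list(grid = traj$grid, seed = traj$seed,
               params = p[setdiff(names(p), "springs")],
               springs = unclass(p$springs))
  fj <- paste0(basename, ".json"); fc <- paste0(basename, ".csv")
  jsonlite::write_json(meta, fj, auto_unbox = TRUE, digits = NA)
  summ <- do.call(rbind, lapply(seq_along(traj$times), function(i) {
    s <- traj$snapshots[[i]]
    data.frame(time = traj$times[i],
               sd_z = stats::sd(as.vector(s$z)),
               z_q10 = stats::quantile(s$z, 0.1),
               z_q90 = stats::quantile(s$z, 0.9),
               mean_C = mean(s$C), mean_I = mean(s$I))
  }))
  utils::write.csv(summ, fc, row.names = FALSE)
  invisible(c(fj, fc))
}

#' Close-contact patch statistics of a thermally rough membrane
#'
#' Models the pre-patterning membrane separation as a stationary Gaussian
#' random field (squared-exponential correlation) and reports the excursion
#' statistics below a close-contact threshold: area fraction (with the
#' normal-tail closed form for comparison), mean patch equivalent-circle
#' diameter, and patch density, averaged over Monte-Carlo replicates
#' (8-connected components).
#'
#' @param mean_sep Mean separation, nm.
#' @param sd_sep SD of the separation field, nm.
#' @param corr_len Correlation length of the field, nm.
#' @param threshold Close-contact threshold, nm.
#' @param domain_nm Side of the square simulated domain, nm.
#' @param grid_nm Grid spacing, nm (must resolve `corr_len`).
#' @param n_rep Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return A list with `area_fraction`, `area_fraction_se`,
#'   `area_fraction_closed_form`, `mean_patch_diameter_nm`,
#'   `patch_density_um2`, and `n_patches_total`.
#' @export
close_contact_patch_stats <- function(mean_sep = 18, sd_sep = 3,
                                      corr_len = 20, threshold = 12,
                                      domain_nm = 2000, grid_nm = 5,
                                      n_rep = 8, seed = 1) {
  stopifnot(sd_sep > 0, corr_len > grid_nm)
  n <- ceiling(domain_nm / grid_nm)
  fr <- dia <- den <- par <- numeric(n_rep)
  n_tot <- 0
  for (r in seq_len(n_rep)) {
    g <- gaussian_random_field(n, n, corr_len / grid_nm, seed = seed + r - 1)
    sep <- mean_sep + sd_sep * g
    mask <- sep < threshold
    fr[r] <- mean(mask)
    lab <- label_components(mask, connectivity = 8)
    np <- max(lab)
    n_tot <- n_tot + np
    if (np > 0) {
      areas <- tabulate(lab[lab > 0], nbins = np) * grid_nm^2
      dia[r] <- mean(2 * sqrt(areas / pi))
      par[r] <- mean(areas)
      den[r] <- np / (domain_nm / 1000)^2
    }
  }
  list(area_fraction = mean(fr),
       area_fraction_se = stats::sd(fr) / sqrt(n_rep),
       area_fraction_closed_form = stats::pnorm((threshold - mean_sep) / sd_sep),
       mean_patch_diameter_nm = mean(dia[dia > 0]),
       mean_patch_area_nm2 = mean(par[par > 0]),
       patch_density_um2 = mean(den),
       n_patches_total = n_tot)
}

#' 2D dissociation constant from the optimal complex enrichment
#'
#' At the optimal separation, mass action gives `K_d = R * L_fs / B_opt`
#' with `R` the free receptor density in the interface and `L_fs` the free
#' ligand density. An order-of-magnitude estimate: 2D densities fluctuate
#' and the confinement width is environment dependent.
#'
#' @param B_opt Optimal complex density, um^-2 (> 0).
#' @param L_fs Free small-ligand density, um^-2.
#' @param R_density Free receptor density in the interface, um^-2.
#' @return A list with `Kd_um2` and `order_of_magnitude_only = TRUE`.
#' @export
kd_2d_from_enrichment <- function(B_opt, L_fs, R_density) {
  if (any(c(B_opt, L_fs, R_density) <= 0))
    stop("densities must be positive (B_opt = 0 is degenerate)")
  list(Kd_um2 = R_density * L_fs / B_opt, order_of_magnitude_only = TRUE)
}

#' Homogeneous-mode growth rate of a uniform state
#'
#' Largest real eigenvalue of the reservoir-coupled homogeneous dynamics in
#' (complex density, separation); positive means the state is unstable even
#' without spatial structure (the middle state of a bistable composition).
#'
#' @param state A `"steady_state"`.
#' @param p A [dynamics_params()] object.
#' @return Growth rate, s^-1.
#' @export
homogeneous_growth_rate <- function(state, p) {
  stopifnot(inherits(state, "steady_state"), inherits(p, "dynamics_params"))
  max(Re(eigen(homogeneous_jacobian(state, p), only.values = TRUE)$values))
}
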