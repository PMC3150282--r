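# Spring-energy parametrisation, Boltzmann concentration <-> energy mapping,
# and the square-root-energy (SQRE) linear relation.
#
# Units throughout: lengths nm, energies kT (thermal energy absorbed into the
# spring constants), concentrations um^-2, time s.

#' Spring parameters of the size-exclusion model
#'
#' Bundles the quadratic spring energies of the short receptor--ligand complex
#' and of the long unbound ligand (ICAM1-like). The complex has natural bond
#' length `z_C` (12--14 nm for CD2--CD58 or KIR--HLA end-on binding) and the
#' long ligand an exodomain length `z_I` (18 nm for ICAM1). A local membrane
#' separation `z` costs `E_C(z) = lambda_C * (z - z_C)^2` for the complex and
#' `E_I(z) = lambda_I * (z - z_I)^2` for the long ligand.
#'
#' @param lambda_C Spring constant of the complex, kT nm^-2 (> 0).
#' @param lambda_I Spring constant of the long ligand, kT nm^-2 (> 0).
#' @param z_C Natural bond length of the complex, nm (0 < z_C < z_I).
#' @param z_I Exodomain length of the long ligand, nm.
#' @return An object of class `"spring_params"`.
#' @examples
#' sp <- spring_params()
#' spring_energy(15, sp, "complex")
#' @export
spring_params <- function(lambda_C = 0.1024 / 0.49, lambda_I = 0.1024,
                          z_C = 13, z_I = 18) {
  stopifnot(is.numeric(lambda_C), is.numeric(lambda_I),
            length(lambda_C) == 1L, length(lambda_I) == 1L,
            length(z_C) == 1L, length(z_I) == 1L)
  if (lambda_C <= 0 || lambda_I <= 0)
    stop("spring constants must be positive")
  if (!(0 < z_C && z_C < z_I))
    stop("natural lengths must satisfy 0 < z_C < z_I")
  structure(list(lambda_C = lambda_C, lambda_I = lambda_I,
                 z_C = z_C, z_I = z_I),
            class = "spring_params")
}

#' @export
print.spring_params <- function(x, ...) {
  cat("Spring parameters (quadratic exclusion energies)\n")
  cat(sprintf("  complex:     lambda_C = %.4g kT/nm^2, z_C = %.3g nm\n",
              x$lambda_C, x$z_C))
  cat(sprintf("  long ligand: lambda_I = %.4g kT/nm^2, z_I = %.3g nm\n",
              x$lambda_I, x$z_I))
  ln <- sqre_line_from_springs(x)
  cat(sprintf("  implied SQRE line: e_I = %.4g - %.4g * e_C\n",
              ln$alpha, ln$beta))
  invisible(x)
}

#' Quadratic spring energy of a species at a given membrane separation
#'
#' @param z Membrane separation, nm (> 0); vectorised.
#' @param p A [spring_params()] object.
#' @param species `"complex"` or `"long_ligand"`.
#' @return Energy in kT, zero at the species' natural length.
#' @export
spring_energy <- function(z, p, species = c("complex", "long_ligand")) {
  species <- match.arg(species)
  stopifnot(inherits(p, "spring_params"))
  if (any(!is.finite(z)) || any(z <= 0))
    stop("membrane separation z must be positive and finite")
  if (species == "complex") p$lambda_C * (z - p$z_C)^2
  else p$lambda_I * (z - p$z_I)^2
}

#' Separation-dependent complex off-rate
#'
#' The bond dissociation rate grows with the spring energy stored in the
#' stretched/compressed complex, `koff(z) = koff0 * exp(E_C(z))`; the on-rate
#' is held constant.
#'
#' @param z Membrane separation, nm; vectorised.
#' @param p A [spring_params()] object.
#' @param koff0 Intrinsic off-rate at the natural bond length, s^-1 (> 0).
#' @return Off-rate in s^-1.
#' @export
off_rate <- function(z, p, koff0) {
  stopifnot(length(koff0) == 1L, is.finite(koff0))
  if (koff0 <= 0) stop("koff0 must be positive")
  koff0 * exp(spring_energy(z, p, "complex"))
}

#' Boltzmann concentration at a given exclusion energy
#'
#' Equating chemical potentials with a reference (optimal-environment)
#' concentration gives `conc = ref_conc * exp(-E)`.
#'
#' @param E Exclusion energy, kT (>= 0); vectorised.
#' @param ref_conc Reference concentration, um^-2 (>= 0).
#' @return Concentration in um^-2.
#' @export
boltzmann_concentration <- function(E, ref_conc) {
  if (any(!is.finite(E)) || any(E < 0))
    stop("exclusion energy must be finite and non-negative")
  if (any(ref_conc < 0)) stop("reference concentration must be non-negative")
  ref_conc * exp(-E)
}

#' Exclusion energy from an observed concentration
#'
#' Inverse of [boltzmann_concentration()]: `E = -log(conc / ref_conc)`.
#' Concentrations above the reference are non-physical enrichment and signal
#' an error unless `clamp = TRUE`, in which case they are clamped to E = 0
#' with a warning.
#'
#' @param conc Observed concentration, um^-2 (0 < conc <= ref_conc).
#' @param ref_conc Reference concentration, um^-2.
#' @param clamp Clamp enrichment above the reference to zero energy?
#' @return Exclusion energy in kT (>= 0).
#' @export
energy_from_concentration <- function(conc, ref_conc, clamp = FALSE) {
  if (any(conc <= 0)) stop("concentration must be positive")
  bad <- conc > ref_conc
  if (any(bad)) {
    if (!clamp)
      stop(sprintf("%d value(s) exceed the reference concentration %s",
                   sum(bad), "(non-physical enrichment); use clamp = TRUE to clamp"))
    warning(sprintf("clamping %d enriched value(s) to E = 0", sum(bad)))
    conc <- pmin(conc, ref_conc)
  }
  -log(conc / ref_conc)
}

#' SQRE regression line implied by the spring parameters
#'
#' Eliminating the unobserved membrane separation from the two quadratic
#' energies links the square-root energies linearly:
#' `e_I = alpha - beta * e_C` for separations between the two natural lengths,
#' with `beta = sqrt(lambda_I / lambda_C)` and
#' `alpha = sqrt(lambda_I) * (z_I - z_C)`. Mutual exclusion selects the
#' positive (physical) root, hence the negative slope.
#'
#' @param p A [spring_params()] object.
#' @return An object of class `"sqre_line"` with fields `alpha` (intercept,
#'   kT^1/2) and `beta` (slope magnitude, dimensionless).
#' @export
sqre_line_from_springs <- function(p) {
  stopifnot(inherits(p, "spring_params"))
  sqre_line(alpha = sqrt(p$lambda_I) * (p$z_I - p$z_C),
            beta = sqrt(p$lambda_I / p$lambda_C))
}

#' Construct an SQRE regression line `e_I = alpha - beta * e_C`
#'
#' @param alpha Intercept, kT^1/2 (> 0).
#' @param beta Slope magnitude, dimensionless (> 0).
#' @return An object of class `"sqre_line"`.
#' @export
sqre_line <- function(alpha, beta) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L,
            is.finite(alpha), is.finite(beta))
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta), class = "sqre_line")
}

#' @export
print.sqre_line <- function(x, ...) {
  cat(sprintf("SQRE line: e_I = %.4g - %.4g * e_C  (e_C intercept %.4g)\n",
              x$alpha, x$beta, x$alpha / x$beta))
  invisible(x)
}

#' Normalised membrane separation from the complex SQRE
#'
#' Reconstructs the hidden separation variable on the physical branch
#' `z >= z_C`, rescaled so 0 corresponds to the complex bond length and 1 to
#' the long-ligand exodomain length:
#' `z_hat = e_C / (sqrt(lambda_C) * (z_I - z_C))`.
#'
#' @param e_C Complex SQRE, kT^1/2 (>= 0); vectorised.
#' @param p A [spring_params()] object.
#' @return Dimensionless normalised separation `z_hat`.
#' @export
separation_from_sqre <- function(e_C, p) {
  stopifnot(inherits(p, "spring_params"))
  if (any(e_C < 0)) stop("SQRE must be non-negative")
  e_C / (sqrt(p$lambda_C) * (p$z_I - p$z_C))
}

#' Effective spring constant of a tension + rigidity membrane sheet
#'
#' The membrane supporting a bound complex responds to a point load like a
#' spring. For an elastic sheet with bending rigidity `kappa` and surface
#' tension `sigma`, the displacement under a point force F, measured at the
#' protein radius `a` relative to the sheet at the elastic screening length
#' `l = sqrt(kappa/sigma)`, is
#' `z(a) - z(l) = F / (2 pi sigma) * (log(l/a) - K0(a/l) + K0(1))`,
#' giving `k_eff = 2 pi sigma / (log(l/a) - K0(a/l) + K0(1))`. The bending
#' term regularises the point load, so for `a << l` the constant depends only
#' weakly on `a`.
#'
#' @param kappa Bending rigidity, kT (> 0).
#' @param sigma Surface tension, kT nm^-2 (> 0).
#' @param a Radius of the protein in the membrane, nm (> 0); the result is
#'   only meaningful for `a` well below `sqrt(kappa/sigma)`.
#' @return A list with `value` (effective spring constant, kT nm^-2),
#'   `length_scale` (`sqrt(kappa/sigma)`, nm) and `valid` (FALSE, with a
#'   warning, when `a` is not small compared to the screening length).
#' @export
effective_spring_constant <- function(kappa = 25, sigma = 0.0024, a = 5) {
  stopifnot(kappa > 0, sigma > 0, a > 0)
  l <- sqrt(kappa / sigma)
  valid <- a < 0.5 * l
  if (!valid)
    warning("protein radius is not small compared to sqrt(kappa/sigma); ",
            "the sheet model is outside its validity range")
  denom <- log(l / a) - besselK(a / l, 0) + besselK(1, 0)
  list(value = 2 * pi * sigma / denom, length_scale = l, valid = valid)
}
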