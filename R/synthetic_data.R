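# Ground-truth generator: 2D bilayer images and 3D confocal-like z-stacks
# whose counts are drawn from the exact observation-model means, plus a
# step-potential phantom for PSF studies. Every generated object carries its
# full truth (separation field, energies, masks, spec, seed) so inference
# output can be scored without re-derivation. RNG: R's default Mersenne
# Twister, seeded explicitly; all outputs are deterministic per seed.

#' Sample a latent membrane-separation field
#'
#' Modes: `"two_phase"` produces blobby domains near the two natural lengths
#' with smoothed (diffuse) walls, by soft-thresholding a squared-exponential
#' Gaussian random field; `"smooth_grf"` maps the field smoothly onto the
#' interval between the natural lengths; `"uniform"` is a constant field.
#'
#' @param mode `"two_phase"`, `"smooth_grf"` or `"uniform"`.
#' @param springs A [spring_params()] object (supplies z_C, z_I).
#' @param nrow,ncol Grid size in pixels.
#' @param seed Integer seed.
#' @param corr_len Correlation length of the latent field, pixels.
#' @param close_contact_frac Fraction of the field in the close-contact
#'   (z near z_C) phase (`two_phase` only).
#' @param wall_width Wall diffuseness (in SD units of the latent Gaussian
#'   field); larger is smoother (`two_phase` only).
#' @param z_const Separation used by `"uniform"` mode, nm.
#' @return Matrix of separations z in nm, bounded in `[z_C, z_I]`.
#' @export
sample_separation_field <- function(mode = c("two_phase", "smooth_grf", "uniform"),
                                    springs = spring_params(),
                                    nrow = 64, ncol = 64, seed = 1,
                                    corr_len = 4, close_contact_frac = 0.55,
                                    wall_width = 0.8,
                                    z_const = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(springs, "spring_params"), nrow >= 1, ncol >= 1)
  z_C <- springs$z_C; z_I <- springs$z_I
  if (mode == "uniform") {
    if (is.null(z_const)) z_const <- (z_C + z_I) / 2
    return(matrix(z_const, nrow, ncol))
  }
  g <- gaussian_random_field(nrow, ncol, corr_len, seed = seed)
  if (mode == "two_phase") {
    thr <- stats::qnorm(close_contact_frac)
    s <- stats::plogis((thr - g) / wall_width)  # 1 in close-contact blobs
    z_I + (z_C - z_I) * s
  } else {
    z_C + (z_I - z_C) * stats::pnorm(g)
  }
}

# Stationary Gaussian random field with squared-exponential correlation
# exp(-d^2 / (2 corr_len^2)) and unit marginal variance, by spectral
# synthesis (Gaussian smoothing of white noise in Fourier space, periodic).
gaussian_random_field <- function(nrow, ncol, corr_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (corr_len <= 0) return(w)
  sk <- corr_len / sqrt(2)
  fx <- c(0:(nrow %/% 2), -((ceiling(nrow / 2) - 1):1)) / nrow
  fy <- c(0:(ncol %/% 2), -((ceiling(ncol / 2) - 1):1)) / ncol
  gx <- exp(-2 * pi^2 * sk^2 * fx^2)
  gy <- exp(-2 * pi^2 * sk^2 * fy^2)
  filt <- outer(gx, gy)
  f <- stats::fft(stats::fft(w) * filt, inverse = TRUE) / (nrow * ncol)
  f <- Re(f)
  f / sqrt(sum(filt^2) / (nrow * ncol))
}

#' Generate a synthetic two-colour bilayer image with known truth
#'
#' Free-surface pixels are homogeneous draws at the free-surface means;
#' contact-interface pixels have means modulated per pixel by the exclusion
#' energies implied by a latent separation field and the spring parameters
#' (the forward direction of the observation model). The default layout is a
#' 64 x 64 image with a central circular contact interface of about 2000
#' pixels surrounded by free surface (with a 2-pixel guard ring excluded
#' from both regions).
#'
#' @param spec A [fluor_spec()] object (observation model; defaults are
#'   calibrated so the contact-interface channel correlation of the default
#'   image falls in the empirically observed band, about -0.4 to -0.7).
#' @param springs A [spring_params()] object (defaults give SQRE line
#'   beta = 0.7, alpha = 1.6).
#' @param nrow,ncol Image size, pixels.
#' @param field_mode,corr_len,close_contact_frac,wall_width Passed to
#'   [sample_separation_field()].
#' @param psf_sigma Optional Gaussian PSF sigma in pixels; when positive the
#'   mean fields are blurred before noise is drawn.
#' @param seed Integer seed.
#' @return A list with class `"synthetic_bilayer"`: `image`
#'   (a [two_channel_image()]), `masks` (a [region_masks()]), and `truth`
#'   (separation field `z`, per-pixel `E_C`, `E_I`, `e_C`, `e_I` matrices,
#'   `spec`, `springs`, `line`, `seed`).
#' @export
generate_bilayer <- function(spec = fluor_spec(), springs = spring_params(),
                             nrow = 64, ncol = 64,
                             field_mode = "two_phase", corr_len = 4,
                             close_contact_frac = 0.55, wall_width = 0.8,
                             psf_sigma = 0, seed = 1) {
  stopifnot(inherits(spec, "fluor_spec"), inherits(springs, "spring_params"))
  set.seed(seed)
  z <- sample_separation_field(field_mode, springs, nrow, ncol,
                               seed = seed, corr_len = corr_len,
                               close_contact_frac = close_contact_frac,
                               wall_width = wall_width)
  E_C <- spring_energy(z, springs, "complex")
  E_I <- spring_energy(z, springs, "long_ligand")
  e_C <- sqrt(E_C); e_I <- sqrt(E_I)

  cx <- (nrow + 1) / 2; cy <- (ncol + 1) / 2
  r_ci <- sqrt(nrow * ncol / 2 / pi)          # ci covers ~half the pixels
  d <- sqrt(outer((seq_len(nrow) - cx)^2, (seq_len(ncol) - cy)^2, `+`))
  ci <- d <= r_ci
  fs <- d > r_ci + 2
  masks <- region_masks(free_surface = fs, contact_interface = ci)

  m_s <- matrix(spec$mu_fs_small + spec$bg_small, nrow, ncol)
  m_l <- matrix(spec$mu_fs_long + spec$bg_long, nrow, ncol)
  m_s[ci] <- ci_mean_small(spec, e_C[ci])
  m_l[ci] <- ci_mean_long(spec, e_I[ci])
  if (psf_sigma > 0) {
    m_s <- gaussian_blur(m_s, psf_sigma)
    m_l <- gaussian_blur(m_l, psf_sigma)
  }
  img <- two_channel_image(draw_counts(m_s, spec), draw_counts(m_l, spec))

  structure(list(image = img, masks = masks,
                 truth = list(z = z, E_C = E_C, E_I = E_I,
                              e_C = e_C, e_I = e_I,
                              spec = spec, springs = springs,
                              line = sqre_line_from_springs(springs),
                              seed = seed)),
            class = "synthetic_bilayer")
}

# Draw counts from the spec's noise family around the given means.
draw_counts <- function(means, spec) {
  n <- length(means)
  out <- switch(spec$noise_family,
    poisson = stats::rpois(n, means),
    gaussian = pmax(0, stats::rnorm(n, means, sqrt(spec$dispersion * means))),
    gamma = stats::rgamma(n, shape = spec$dispersion,
                          scale = means / spec$dispersion))
  array(out, dim = dim(means))
}

#' Generate a synthetic 3D z-stack of a cell conjugate with known truth
#'
#' Emulates a confocal stack of a roughly spherical cell pressed flat against
#' a neighbour: the membrane is a spherical shell with a Gaussian
#' cross-section (apparent thickness, wider on the free surface than in the
#' contact interface), truncated by a flat contact cap. Long-ligand intensity
#' on the cap is attenuated by the exclusion energies of a latent separation
#' field over the cap; noise is Gamma by default (the family that fits
#' cell-conjugate data).
#'
#' @param spec A [fluor_spec()] object; default switches to Gamma noise.
#' @param springs A [spring_params()] object.
#' @param nx,ny,nz Stack dimensions (rows, cols, slices).
#' @param radius_px Cell radius, xy pixels.
#' @param cap_depth_px How deep the flattening plane cuts into the cell,
#'   xy pixels.
#' @param anisotropy Slice spacing in units of xy pixels (360/93 for
#'   93 x 93 x 360 nm voxels).
#' @param seed Integer seed.
#' @return A list with class `"synthetic_zstack"`: `image` (3D
#'   [two_channel_image()]), `truth` (per-slice contour chains, region labels
#'   along each contour, membrane distance field, separation field over the
#'   cap, spec, springs, seed).
#' @export
generate_zstack <- function(spec = fluor_spec(mu_fs_small = 120,
                                              mu_fs_long = 200, A_B = 250,
                                              Gamma_barrier = 0.86,
                                              bg_small = 40, bg_long = 40,
                                              noise_family = "gamma",
                                              dispersion = 15),
                            springs = spring_params(),
                            nx = 48, ny = 48, nz = 13,
                            radius_px = 16, cap_depth_px = 6,
                            anisotropy = 360 / 93, seed = 1) {
  stopifnot(inherits(spec, "fluor_spec"))
  set.seed(seed)
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  cz <- (nz + 1) / 2
  x0 <- cy + radius_px - cap_depth_px   # flattening plane (column index)
  if (x0 + 2 > ny || cx - radius_px < 3 || cx + radius_px > nx - 2 ||
      cy - radius_px < 3)
    stop("cell geometry does not fit in the volume with margin")
  cap_r2 <- radius_px^2 - (radius_px - cap_depth_px)^2

  # latent separation over the cap, indexed by (row, slice)
  zsep <- sample_separation_field("two_phase", springs,
                                  nrow = nx, ncol = nz, seed = seed,
                                  corr_len = 3, close_contact_frac = 0.7)
  e_C_cap <- sqrt(spring_energy(zsep, springs, "complex"))
  e_I_cap <- sqrt(spring_energy(zsep, springs, "long_ligand"))

  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  m_small <- array(spec$bg_small, c(nx, ny, nz))
  m_long <- array(spec$bg_long, c(nx, ny, nz))
  dist_mem <- array(Inf, c(nx, ny, nz))
  region <- array(0L, c(nx, ny, nz))  # 1 fs, 2 ci (nearest membrane element)
  for (k in zs) {
    dz <- (k - cz) * anisotropy
    rk2 <- radius_px^2 - dz^2
    if (rk2 <= 1) next
    dxy <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`) + dz^2)
    d_sph <- abs(dxy - radius_px)
    xcol <- matrix(rep(ys, each = nx), nx, ny)
    in_cap_proj <- outer((xs - cx)^2, rep(1, ny)) + dz^2 <= cap_r2
    d_cap <- abs(xcol - x0)
    d_cap[!in_cap_proj] <- Inf
    d_sph[xcol > x0] <- Inf            # sphere surface removed beyond the cap
    use_cap <- d_cap < d_sph
    dmin <- pmin(d_sph, d_cap)
    dist_mem[, , k] <- dmin
    reg <- ifelse(use_cap, 2L, 1L)
    reg[!is.finite(dmin)] <- 0L
    region[, , k] <- reg
    att_fs <- exp(-dmin^2 / (2 * spec$thickness_fs^2))
    att_ci <- exp(-dmin^2 / (2 * spec$thickness_ci^2))
    amp_s_fs <- spec$mu_fs_small
    amp_l_fs <- spec$mu_fs_long
    amp_s_ci <- ci_mean_small(spec, e_C_cap[, k]) - spec$bg_small
    amp_l_ci <- ci_mean_long(spec, e_I_cap[, k]) - spec$bg_long
    ms <- ifelse(use_cap, matrix(amp_s_ci, nx, ny) * att_ci, amp_s_fs * att_fs)
    ml <- ifelse(use_cap, matrix(amp_l_ci, nx, ny) * att_ci, amp_l_fs * att_fs)
    ms[reg == 0L] <- 0; ml[reg == 0L] <- 0
    m_small[, , k] <- spec$bg_small + ms
    m_long[, , k] <- spec$bg_long + ml
  }
  img <- two_channel_image(draw_counts(m_small, spec), draw_counts(m_long, spec),
                           pixel_size_nm = 93,
                           voxel_size_nm = c(93, 93, 360))
  contours <- lapply(zs, function(k) {
    dz <- (k - cz) * anisotropy
    rk2 <- radius_px^2 - dz^2
    if (rk2 <= 4) return(NULL)
    slice_contour_chain(cx, cy, sqrt(rk2), x0, nx, ny)
  })
  structure(list(image = img,
                 truth = list(contours = contours, region = region,
                              dist_mem = dist_mem, z_cap = zsep,
                              e_C_cap = e_C_cap, e_I_cap = e_I_cap,
                              centre = c(cx, cx, cz), radius_px = radius_px,
                              plane_col = x0, anisotropy = anisotropy,
                              spec = spec, springs = springs, seed = seed)),
            class = "synthetic_zstack")
}

# Ordered, closed, 8-connected contour chain for a circle of radius r centred
# at (cx, cy), clipped by the flat chord at column x0 (contact cap). Returns a
# matrix of (row, col) pixel indices plus a region label per vertex
# (1 free surface, 2 contact interface).
slice_contour_chain <- function(cx, cy, r, x0, nx, ny) {
  n <- max(64, ceiling(8 * r))
  if (x0 >= cy + r) {           # no cap in this slice: full circle
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    px <- cx + r * sin(th)
    py <- cy + r * cos(th)
    lab_f <- rep(1L, n)
  } else {
    thc <- acos((x0 - cy) / r)  # circle meets the chord at +-thc
    th <- seq(thc, 2 * pi - thc, length.out = n)
    px <- cx + r * sin(th)
    py <- cy + r * cos(th)
    half <- r * sin(thc)
    nch <- max(2, ceiling(2 * half))
    ch_rows <- seq(cx - half, cx + half, length.out = nch)
    px <- c(px, ch_rows)
    py <- c(py, rep(x0, nch))
    lab_f <- c(rep(1L, n), rep(2L, nch))
  }
  ij <- cbind(round(px), round(py))
  ij[, 1] <- pmax(1, pmin(nx, ij[, 1]))
  ij[, 2] <- pmax(1, pmin(ny, ij[, 2]))
  keep <- c(TRUE, rowSums(abs(diff(ij))) > 0)
  list(chain = ij[keep, , drop = FALSE], region = lab_f[keep])
}

#' Step-potential phantom with Gaussian PSF blur
#'
#' A sharp two-phase truth (a vertical domain wall separating two discrete
#' energy levels) is forwarded through the observation model, blurred with a
#' Gaussian PSF, and optionally degraded with Poisson noise. Because the true
#' energies take only two values, any spread along a line in SQRE coordinates
#' of the fitted per-pixel energies of the blurred image is an artifact of
#' the PSF, which is what this phantom quantifies.
#'
#' @param spec A [fluor_spec()] object.
#' @param springs A [spring_params()] object.
#' @param nrow,ncol Image size.
#' @param z_levels Length-2 separations (nm) of the two phases.
#' @param psf_sigma Gaussian PSF sigma, pixels (0 = no blur).
#' @param noise Draw Poisson noise after blurring?
#' @param seed Integer seed.
#' @return A list with class `"step_phantom"`: `image`, `masks` (all-ci with
#'   a free-surface frame), `psf` (normalised PSF image), and `truth`
#'   (phase map, per-phase energies, blurred and unblurred mean fields).
#' @export
step_phantom_and_blur <- function(spec = fluor_spec(), springs = spring_params(),
                                  nrow = 48, ncol = 48,
                                  z_levels = NULL, psf_sigma = 1.5,
                                  noise = TRUE, seed = 1) {
  stopifnot(inherits(spec, "fluor_spec"))
  set.seed(seed)
  if (is.null(z_levels))
    z_levels <- c(springs$z_C + 0.5, springs$z_I - 0.5)
  stopifnot(length(z_levels) == 2)
  phase <- matrix(rep(c(1L, 2L), each = nrow * ncol / 2), nrow, ncol)
  z <- matrix(z_levels[phase], nrow, ncol)
  e_C <- sqrt(spring_energy(z, springs, "complex"))
  e_I <- sqrt(spring_energy(z, springs, "long_ligand"))
  m_s0 <- matrix(ci_mean_small(spec, e_C), nrow, ncol)
  m_l0 <- matrix(ci_mean_long(spec, e_I), nrow, ncol)
  if (psf_sigma > 0) {
    m_s <- gaussian_blur(m_s0, psf_sigma)
    m_l <- gaussian_blur(m_l0, psf_sigma)
  } else {
    m_s <- m_s0; m_l <- m_l0
  }
  small <- if (noise) array(stats::rpois(length(m_s), m_s), dim(m_s)) else m_s
  long <- if (noise) array(stats::rpois(length(m_l), m_l), dim(m_l)) else m_l
  ci <- matrix(TRUE, nrow, ncol)
  fs <- matrix(FALSE, nrow, ncol)
  psf <- gaussian_psf(psf_sigma, max(3, ceiling(3 * max(psf_sigma, 1))))
  structure(list(image = two_channel_image(small, long),
                 masks = region_masks(fs, ci),
                 psf = psf,
                 truth = list(phase = phase, z_levels = z_levels,
                              e_C_levels = sqrt(spring_energy(z_levels, springs, "complex")),
                              e_I_levels = sqrt(spring_energy(z_levels, springs, "long_ligand")),
                              mean_small = m_s0, mean_long = m_l0,
                              mean_small_blur = m_s, mean_long_blur = m_l,
                              psf_sigma = psf_sigma, spec = spec,
                              springs = springs, seed = seed)),
            class = "step_phantom")
}

# Normalised Gaussian PSF image with half-width hw (odd size 2*hw + 1).
gaussian_psf <- function(sigma, hw) {
  x <- -hw:hw
  if (sigma <= 0) {
    k <- matrix(0, 2 * hw + 1, 2 * hw + 1)
    k[hw + 1, hw + 1] <- 1
    return(k)
  }
  k <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  k / sum(k)
}
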