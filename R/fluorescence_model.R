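# Observation model for two-colour photon counts: free-surface pixels have
# homogeneous means, contact-interface pixels have means modulated by the
# per-pixel exclusion energies through the Boltzmann factor. Noise families:
# Poisson (default for bilayer data), Gaussian with variance proportional to
# the mean (photon statistics with gain), or Gamma (captures the skew seen in
# cell-conjugate free surfaces).

#' Global parameters of the fluorescence observation model
#'
#' The bilayer model has a small number of global parameter combinations:
#' free-surface mean counts for each channel (emission efficiency times
#' concentration; the two are never separable and only their product is
#' exposed), the optimal-binding complex amplitude `A_B`, a barrier factor
#' `Gamma_barrier` in (0, 1] discounting the free small-ligand density inside
#' the contact interface, and per-channel backgrounds. The small channel
#' contact-interface mean at complex SQRE `e_C` is
#' `Gamma_barrier * mu_fs_small + A_B * exp(-e_C^2) + bg_small`; the long
#' channel mean at SQRE `e_I` is `mu_fs_long * exp(-e_I^2) + bg_long`.
#' Free-surface means are `mu_fs_* + bg_*`.
#'
#' @param mu_fs_small Free-surface mean counts, small-ligand channel (>= 0).
#' @param mu_fs_long Free-surface mean counts, long-ligand channel (>= 0).
#' @param A_B Optimal-binding complex amplitude, counts (>= 0).
#' @param Gamma_barrier Free-ligand discount factor in the interface, (0, 1].
#' @param bg_small,bg_long Background (autofluorescence) counts per channel.
#' @param noise_family `"poisson"`, `"gaussian"` or `"gamma"`.
#' @param dispersion Family-specific scalar: for `"gaussian"`, variance =
#'   dispersion * mean; for `"gamma"`, the shape parameter (mean preserved,
#'   variance = mean^2 / shape). Ignored for `"poisson"`.
#' @param thickness_fs,thickness_ci Apparent membrane half-widths (Gaussian
#'   sigma, pixels) on free surface and contact interface; 3D stacks only.
#'   The free surface is typically wider than the interface.
#' @return An object of class `"fluor_spec"`.
#' @export
fluor_spec <- function(mu_fs_small = 40, mu_fs_long = 70, A_B = 95,
                       Gamma_barrier = 0.63, bg_small = 190, bg_long = 190,
                       noise_family = c("poisson", "gaussian", "gamma"),
                       dispersion = NULL,
                       thickness_fs = 2.0, thickness_ci = 1.2) {
  noise_family <- match.arg(noise_family)
  if (any(c(mu_fs_small, mu_fs_long, A_B, bg_small, bg_long) < 0))
    stop("means, amplitude and backgrounds must be non-negative")
  if (Gamma_barrier <= 0 || Gamma_barrier > 1)
    stop("Gamma_barrier must lie in (0, 1]")
  if (is.null(dispersion))
    dispersion <- switch(noise_family, poisson = 1, gaussian = 1.5, gamma = 10)
  if (dispersion <= 0) stop("dispersion must be positive")
  if (thickness_fs < thickness_ci)
    warning("membrane apparent thickness is expected to be wider on the ",
            "free surface than in the contact interface")
  structure(list(mu_fs_small = mu_fs_small, mu_fs_long = mu_fs_long,
                 A_B = A_B, Gamma_barrier = Gamma_barrier,
                 bg_small = bg_small, bg_long = bg_long,
                 noise_family = noise_family, dispersion = dispersion,
                 thickness_fs = thickness_fs, thickness_ci = thickness_ci),
            class = "fluor_spec")
}

#' @export
print.fluor_spec <- function(x, ...) {
  cat("Fluorescence observation model\n")
  cat(sprintf("  free surface means: small %.4g + bg %.4g, long %.4g + bg %.4g\n",
              x$mu_fs_small, x$bg_small, x$mu_fs_long, x$bg_long))
  cat(sprintf("  complex amplitude A_B = %.4g, barrier Gamma = %.3g\n",
              x$A_B, x$Gamma_barrier))
  cat(sprintf("  noise family: %s (dispersion %.3g)\n",
              x$noise_family, x$dispersion))
  invisible(x)
}

#' Expected small-channel counts in a contact-interface pixel
#'
#' Free (barrier-discounted) ligand plus bound complex plus background:
#' `Gamma_barrier * mu_fs_small + A_B * exp(-e_C^2) + bg_small`.
#'
#' @param spec A [fluor_spec()] object.
#' @param e_C Complex SQRE, kT^1/2 (>= 0); vectorised.
#' @return Expected counts.
#' @export
ci_mean_small <- function(spec, e_C) {
  stopifnot(inherits(spec, "fluor_spec"))
  if (any(e_C < 0)) stop("SQRE must be non-negative")
  spec$Gamma_barrier * spec$mu_fs_small + spec$A_B * exp(-e_C^2) + spec$bg_small
}

#' Expected long-channel counts in a contact-interface pixel
#'
#' The long ligand is never enriched in the interface; its mean is the
#' free-surface level attenuated by the Boltzmann factor:
#' `mu_fs_long * exp(-e_I^2) + bg_long`.
#'
#' @param spec A [fluor_spec()] object.
#' @param e_I Long-ligand SQRE, kT^1/2 (>= 0); vectorised.
#' @return Expected counts.
#' @export
ci_mean_long <- function(spec, e_I) {
  stopifnot(inherits(spec, "fluor_spec"))
  if (any(e_I < 0)) stop("SQRE must be non-negative")
  spec$mu_fs_long * exp(-e_I^2) + spec$bg_long
}

#' Pixel log-likelihood under the chosen noise family
#'
#' Poisson uses a continuous extension (log-gamma in place of the factorial)
#' so deconvolved non-integer counts remain valid; Gaussian uses variance
#' `dispersion * mean`; Gamma uses shape `dispersion` and scale
#' `mean / dispersion`.
#'
#' @param counts Observed counts (>= 0); vectorised.
#' @param mean Expected counts (> 0); vectorised (recycled).
#' @param spec A [fluor_spec()] object (supplies family and dispersion).
#' @return Log-likelihood per pixel (same length as `counts`).
#' @export
pixel_loglik <- function(counts, mean, spec) {
  stopifnot(inherits(spec, "fluor_spec"))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(mean <= 0)) stop("model mean must be positive")
  switch(spec$noise_family,
    poisson = counts * log(mean) - mean - lgamma(counts + 1),
    gaussian = {
      v <- spec$dispersion * mean
      -0.5 * log(2 * pi * v) - (counts - mean)^2 / (2 * v)
    },
    gamma = {
      k <- spec$dispersion
      th <- mean / k
      # zero counts have zero density under a Gamma; evaluated at a
      # half-count floor so fully excluded pixels stay finite
      x <- pmax(counts, 0.5)
      (k - 1) * log(x) - x / th - k * log(th) - lgamma(k)
    })
}

#' Gaussian transect profile of the apparent membrane thickness (3D model)
#'
#' In a z-stack slice the membrane has an apparent width; expected counts at
#' perpendicular offset `d` pixels from the contour are
#' `amplitude * exp(-d^2 / (2 width^2)) + background`, where the width is
#' region-specific (free surface wider than contact interface) and the
#' amplitude carries the concentration signal at the contour.
#'
#' @param spec A [fluor_spec()] object.
#' @param amplitude Peak counts at the contour.
#' @param offset Perpendicular offset from the contour, pixels; vectorised.
#' @param region `"free_surface"` or `"contact_interface"`.
#' @param background Background counts added to the profile.
#' @return Expected counts.
#' @export
thickness_profile <- function(spec, amplitude, offset,
                              region = c("free_surface", "contact_interface"),
                              background = 0) {
  stopifnot(inherits(spec, "fluor_spec"))
  region <- match.arg(region)
  w <- if (region == "free_surface") spec$thickness_fs else spec$thickness_ci
  if (w <= 0) stop("membrane apparent thickness must be positive")
  amplitude * exp(-offset^2 / (2 * w^2)) + background
}

#' Total image log-likelihood
#'
#' Sums pixel log-likelihoods over the free surface (homogeneous means per
#' channel) and the contact interface (per-pixel energy-modulated means). In
#' 3D mode (`offsets` supplied) every pixel mean is additionally attenuated
#' by the Gaussian thickness profile of its region.
#'
#' @param img A `two_channel_image` (see [two_channel_image()]).
#' @param masks A `region_masks` object (see [region_masks()]).
#' @param e_C,e_I Per-pixel SQREs for the contact-interface pixels, in the
#'   order given by `which(masks$contact_interface)`.
#' @param spec A [fluor_spec()] object.
#' @param offsets Optional per-pixel perpendicular offsets (pixels) for both
#'   regions, same layout as the image, for the 3D thickness model.
#' @return Total log-likelihood (scalar).
#' @export
image_loglik <- function(img, masks, e_C, e_I, spec, offsets = NULL) {
  stopifnot(inherits(img, "two_channel_image"), inherits(masks, "region_masks"),
            inherits(spec, "fluor_spec"))
  fs <- masks$free_surface
  ci <- masks$contact_interface
  if (!any(fs) || !any(ci)) stop("both regions must contain pixels")
  n_ci <- sum(ci)
  stopifnot(length(e_C) == n_ci, length(e_I) == n_ci)
  m_fs_s <- spec$mu_fs_small + spec$bg_small
  m_fs_l <- spec$mu_fs_long + spec$bg_long
  m_ci_s <- ci_mean_small(spec, e_C)
  m_ci_l <- ci_mean_long(spec, e_I)
  if (!is.null(offsets)) {
    att_fs <- exp(-offsets[fs]^2 / (2 * spec$thickness_fs^2))
    att_ci <- exp(-offsets[ci]^2 / (2 * spec$thickness_ci^2))
    m_fs_s <- (m_fs_s - spec$bg_small) * att_fs + spec$bg_small
    m_fs_l <- (m_fs_l - spec$bg_long) * att_fs + spec$bg_long
    m_ci_s <- (m_ci_s - spec$bg_small) * att_ci + spec$bg_small
    m_ci_l <- (m_ci_l - spec$bg_long) * att_ci + spec$bg_long
  }
  sum(pixel_loglik(img$small[fs], m_fs_s, spec)) +
    sum(pixel_loglik(img$long[fs], m_fs_l, spec)) +
    sum(pixel_loglik(img$small[ci], m_ci_s, spec)) +
    sum(pixel_loglik(img$long[ci], m_ci_l, spec))
}

#' Two-channel image container
#'
#' @param small,long Matrices (2D) or 3D arrays (z-stacks) of non-negative
#'   intensities for the small-ligand and long-ligand channels; shapes must
#'   match.
#' @param pixel_size_nm Lateral pixel size in nm (167 nm bilayer default).
#' @param voxel_size_nm For stacks, a length-3 vector (x, y, z) in nm.
#' @param channels Channel names.
#' @return An object of class `"two_channel_image"`.
#' @export
two_channel_image <- function(small, long, pixel_size_nm = 167,
                              voxel_size_nm = NULL,
                              channels = c("small_ligand", "long_ligand")) {
  if (!identical(dim(small), dim(long)))
    stop("channel shapes must match")
  if (any(small < 0) || any(long < 0))
    stop("intensities must be non-negative")
  structure(list(small = small, long = long,
                 pixel_size_nm = pixel_size_nm,
                 voxel_size_nm = voxel_size_nm,
                 channels = channels),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  d <- dim(x$small)
  cat(sprintf("Two-channel image: %s px (%s)\n", paste(d, collapse = " x "),
              paste(x$channels, collapse = " / ")))
  cat(sprintf("  pixel size %.3g nm; mean counts %.3g / %.3g\n",
              x$pixel_size_nm, mean(x$small), mean(x$long)))
  invisible(x)
}

#' Region masks for free surface and contact interface
#'
#' @param free_surface,contact_interface Logical arrays matching the image
#'   shape; must be disjoint.
#' @param contours Optional per-slice ordered contour chains (3D pipeline).
#' @return An object of class `"region_masks"`.
#' @export
region_masks <- function(free_surface, contact_interface, contours = NULL) {
  if (!identical(dim(free_surface), dim(contact_interface)))
    stop("mask shapes must match")
  if (any(free_surface & contact_interface))
    stop("region masks must be disjoint")
  structure(list(free_surface = free_surface,
                 contact_interface = contact_interface,
                 contours = contours),
            class = "region_masks")
}
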