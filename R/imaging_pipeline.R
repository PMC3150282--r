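# Image I/O and preprocessing: flat-field/background correction,
# Richardson-Lucy deconvolution, chromatic-shift correction, contour tracking
# on z-stack slices, region extraction, and descriptive statistics.

#' Flat-field and background correction
#'
#' `(image / flat_field) - background`, clipped at zero. The fraction of
#' clipped pixels is attached as an attribute and a warning is raised when it
#' exceeds 5%.
#'
#' @param image Numeric matrix/array of intensities.
#' @param flat_field Positive scalar or array (recycled) of relative
#'   illumination.
#' @param background Scalar or array of background counts to subtract.
#' @return Corrected image with attribute `"clip_fraction"`.
#' @export
preprocess <- function(image, flat_field = 1, background = 0) {
  if (any(flat_field <= 0)) stop("flat field must be positive")
  out <- image / flat_field - background
  clipped <- mean(out < 0)
  if (clipped > 0.05)
    warning(sprintf("%.1f%% of pixels clipped at zero", 100 * clipped))
  out[out < 0] <- 0
  attr(out, "clip_fraction") <- clipped
  out
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative-update deconvolution for Poisson imaging. The PSF
#' is normalised to unit sum (with a warning if it was not); non-negativity
#' is preserved and total intensity is approximately conserved.
#'
#' @param image Non-negative numeric matrix.
#' @param psf Odd-sized PSF kernel matrix.
#' @param n_iter Number of iterations (>= 1).
#' @return Deconvolved image.
#' @export
richardson_lucy <- function(image, psf, n_iter = 50) {
  stopifnot(is.matrix(image), is.matrix(psf), n_iter >= 1)
  if (any(image < 0)) stop("image must be non-negative")
  s <- sum(psf)
  if (abs(s - 1) > 1e-8) {
    warning("PSF not normalised to unit sum; normalising")
    psf <- psf / s
  }
  psf_m <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf))), drop = FALSE]
  est <- image
  est[est <= 0] <- mean(image[image > 0])  # strictly positive start
  eps <- 1e-12
  for (i in seq_len(n_iter)) {
    denom <- conv2_replicate(est, psf)
    ratio <- image / pmax(denom, eps)
    est <- est * conv2_replicate(ratio, psf_m)
  }
  est
}

# 2D convolution with replicate boundary, via EBImage's FFT filter.
conv2_replicate <- function(x, k) {
  EBImage::filter2(x, k, boundary = "replicate")
}

#' Gaussian blur
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian sigma, pixels.
#' @return Blurred image (replicate boundary).
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  hw <- max(3, ceiling(4 * sigma))
  conv2_replicate(image, gaussian_psf(sigma, hw))
}

#' Chromatic shift correction between two channels
#'
#' Finds the integer (row, col) shift of channel 2 that maximises the
#' magnitude of the Pearson correlation with channel 1 over the overlap
#' (magnitude, because synapse channels are anti-correlated), then applies
#' it. A parabolic interpolation of the correlation surface around the
#' optimum is reported as a subpixel estimate; the applied shift is integer.
#'
#' @param ch1,ch2 Numeric matrices of equal size.
#' @param max_shift_px Search window half-width, pixels (default 3).
#' @return A list with `shift` (integer c(row, col) applied to ch2),
#'   `shift_subpixel` (parabolic refinement), `correlation` (signed Pearson
#'   at the optimum), and `ch2_shifted`.
#' @export
correct_chromatic_shift <- function(ch1, ch2, max_shift_px = 3) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  if (stats::sd(ch1) == 0 || stats::sd(ch2) == 0)
    stop("cannot register a flat (zero-variance) channel")
  sh <- -max_shift_px:max_shift_px
  cc <- matrix(NA_real_, length(sh), length(sh))
  for (i in seq_along(sh)) for (j in seq_along(sh)) {
    s2 <- shift_image(ch2, sh[i], sh[j])
    ok <- !is.na(s2)
    cc[i, j] <- stats::cor(ch1[ok], s2[ok])
  }
  idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
  shift <- c(sh[idx[1]], sh[idx[2]])
  sub <- shift
  for (d in 1:2) {
    k <- idx[d]
    if (k > 1 && k < length(sh)) {
      y <- abs(cc[cbind(if (d == 1) (k - 1):(k + 1) else rep(idx[1], 3),
                        if (d == 2) (k - 1):(k + 1) else rep(idx[2], 3))])
      den <- y[1] - 2 * y[2] + y[3]
      if (is.finite(den) && den < 0) sub[d] <- shift[d] + 0.5 * (y[1] - y[3]) / den
    }
  }
  s2 <- shift_image(ch2, shift[1], shift[2])
  s2[is.na(s2)] <- mean(ch2)
  list(shift = shift, shift_subpixel = sub,
       correlation = cc[idx[1], idx[2]], ch2_shifted = s2)
}

# Integer shift with NA padding; shifting by (dr, dc) moves content down/right.
shift_image <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(NA_real_, n, m)
  rs <- seq_len(n) - dr; cs <- seq_len(m) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= m
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

#' Track the membrane contour in a z-stack slice
#'
#' Ridge-following by polar ray casting: the connected above-threshold
#' component containing `seed_point` defines the cell; from its centroid,
#' rays at fine angular steps locate the intensity ridge (maximum along the
#' ray, parabolic subpixel refinement, light median smoothing), which is then
#' rasterised into an ordered, closed, 8-connected, counter-clockwise pixel
#' chain. A broken ridge (ray maximum below threshold) is an error reporting
#' the gap angle; gaps of at most 2 rays are bridged by interpolation.
#'
#' @param slice Numeric matrix (one z-slice, typically the summed channels).
#' @param seed_point c(row, col) on or near the membrane ridge.
#' @param threshold Intensity threshold separating ridge from background.
#' @return A list with `chain` (n x 2 matrix of (row, col)), `centre`, and
#'   `radius` (per-vertex ridge radius, pixels).
#' @export
track_contour <- function(slice, seed_point, threshold) {
  stopifnot(is.matrix(slice), length(seed_point) == 2)
  mask <- slice >= threshold
  if (!any(mask)) stop("no pixels above threshold")
  lab <- label_components(mask, connectivity = 8)
  seed_lab <- lab[round(seed_point[1]), round(seed_point[2])]
  if (seed_lab == 0) {
    # snap to the nearest above-threshold pixel
    w <- which(mask, arr.ind = TRUE)
    d2 <- (w[, 1] - seed_point[1])^2 + (w[, 2] - seed_point[2])^2
    seed_lab <- lab[w[which.min(d2), , drop = FALSE]]
  }
  comp <- lab == seed_lab
  w <- which(comp, arr.ind = TRUE)
  ctr <- c(mean(w[, 1]), mean(w[, 2]))
  rmax <- max(sqrt((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2)) + 2
  n_th <- max(90, ceiling(8 * rmax))
  th <- seq(0, 2 * pi, length.out = n_th + 1)[-(n_th + 1)]
  rr <- seq(1, rmax, by = 0.25)
  radius <- numeric(n_th)
  ok <- logical(n_th)
  for (i in seq_len(n_th)) {
    pr <- ctr[1] + rr * sin(th[i])
    pc <- ctr[2] + rr * cos(th[i])
    v <- bilinear_sample(slice, pr, pc)
    j <- which.max(v)
    ok[i] <- is.finite(v[j]) && v[j] >= threshold
    # parabolic refinement of the ridge radius
    if (j > 1 && j < length(rr) && ok[i]) {
      den <- v[j - 1] - 2 * v[j] + v[j + 1]
      radius[i] <- rr[j] + if (is.finite(den) && den < 0)
        0.25 * 0.5 * (v[j - 1] - v[j + 1]) / den else 0
    } else radius[i] <- rr[j]
  }
  if (!all(ok)) {
    gaps <- rle(!ok)
    if (max(gaps$lengths[gaps$values]) > max(2, ceiling(n_th / 45)))
      stop(sprintf("membrane ridge broken near angle %.2f rad",
                   th[which(!ok)[1]]))
    radius[!ok] <- stats::approx(th[ok], radius[ok], xout = th[!ok],
                                 rule = 2)$y
  }
  radius <- stats::runmed(radius, 5)
  px <- ctr[1] + radius * sin(th)
  py <- ctr[2] + radius * cos(th)
  ij <- cbind(pmax(1, pmin(nrow(slice), round(px))),
              pmax(1, pmin(ncol(slice), round(py))))
  keep <- c(TRUE, rowSums(abs(diff(ij))) > 0)
  chain <- ij[keep, , drop = FALSE]
  # consistent counter-clockwise orientation via the shoelace signed area
  v1 <- chain[, 1] - ctr[1]; v2 <- chain[, 2] - ctr[2]
  area <- sum(v1 * c(v2[-1], v2[1]) - c(v1[-1], v1[1]) * v2) / 2
  if (area < 0) chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
  list(chain = chain, centre = ctr, radius = radius)
}

bilinear_sample <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r <- pmax(1, pmin(n - 1e-9, r)); c <- pmax(1, pmin(m - 1e-9, c))
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, n); c1 <- pmin(c0 + 1, m)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

#' Extract free-surface / contact-interface regions along stack contours
#'
#' Assigns every voxel within `max_offset` pixels of its slice's contour to
#' the region of the nearest contour vertex (1 = free surface, 2 = contact
#' interface, from the per-vertex annotations), with a signed perpendicular
#' offset (positive toward the cell exterior). Slices without a usable
#' contour are excluded.
#'
#' @param stack A 3D [two_channel_image()] (or any 3D array for shape).
#' @param contours Per-slice list of contour results: each `NULL` or a list
#'   with `chain` (n x 2) and per-vertex `region` labels (1 fs, 2 ci).
#' @param max_offset Maximum perpendicular distance from the contour, pixels.
#' @return A [region_masks()] with 3D masks, plus `transects`: a data.frame
#'   of (row, col, slice, offset, region, vertex).
#' @export
extract_regions <- function(stack, contours, max_offset = 3) {
  arr <- if (inherits(stack, "two_channel_image")) stack$small else stack
  stopifnot(length(dim(arr)) == 3, length(contours) == dim(arr)[3])
  dm <- dim(arr)
  fs <- array(FALSE, dm); ci <- array(FALSE, dm)
  tr <- vector("list", dm[3])
  for (k in seq_len(dm[3])) {
    co <- contours[[k]]
    if (is.null(co) || is.null(co$chain) || nrow(co$chain) < 8) next
    if (is.null(co$region))
      stop("contour annotations (per-vertex region labels) are required")
    if (any(co$region == 2L)) {
      # interface limits must lie on the contour
      stopifnot(all(co$region %in% c(1L, 2L)))
    }
    ctr <- if (!is.null(co$centre)) co$centre
           else c(mean(co$chain[, 1]), mean(co$chain[, 2]))
    rows <- pmax(1, min(co$chain[, 1]) - max_offset):pmin(dm[1], max(co$chain[, 1]) + max_offset)
    cols <- pmax(1, min(co$chain[, 2]) - max_offset):pmin(dm[2], max(co$chain[, 2]) + max_offset)
    grid <- expand.grid(row = rows, col = cols)
    d2 <- outer(grid$row, co$chain[, 1], `-`)^2 +
          outer(grid$col, co$chain[, 2], `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(nrow(grid)), nearest)])
    sel <- dmin <= max_offset
    if (!any(sel)) next
    g <- grid[sel, ]; nv <- nearest[sel]; dv <- dmin[sel]
    reg <- co$region[nv]
    # sign: positive when the pixel is further from the cell centre than
    # its contour vertex (toward the exterior)
    r_pix <- sqrt((g$row - ctr[1])^2 + (g$col - ctr[2])^2)
    r_ver <- sqrt((co$chain[nv, 1] - ctr[1])^2 + (co$chain[nv, 2] - ctr[2])^2)
    sgn <- ifelse(r_pix >= r_ver, 1, -1)
    idx <- cbind(g$row, g$col, k)
    fs[idx[reg == 1L, , drop = FALSE]] <- TRUE
    ci[idx[reg == 2L, , drop = FALSE]] <- TRUE
    tr[[k]] <- data.frame(row = g$row, col = g$col, slice = k,
                          offset = sgn * dv, region = reg, vertex = nv)
  }
  ci_and_fs <- fs & ci
  fs[ci_and_fs] <- FALSE  # ties to the interface never happen by nearest-vertex
  masks <- region_masks(free_surface = fs, contact_interface = ci)
  masks$transects <- do.call(rbind, tr)
  masks
}

#' Pearson correlation between the two channels over a mask
#'
#' Mutual exclusion between the fluorophores shows up as a negative
#' correlation over contact-interface pixels.
#'
#' @param image A [two_channel_image()].
#' @param mask Logical array matching the image shape.
#' @return Pearson correlation coefficient.
#' @export
channel_correlation <- function(image, mask) {
  stopifnot(inherits(image, "two_channel_image"))
  x <- image$small[mask]; y <- image$long[mask]
  if (length(x) < 2) stop("mask must select at least 2 pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a channel over the mask")
  stats::cor(x, y)
}

# 8- or 4-connected component labelling of a logical matrix. Built on
# EBImage::bwlabel (4-connected) plus a union-find merge of labels that
# touch diagonally.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal
  pr <- rbind(cbind(as.vector(a1), as.vector(b1)),
              cbind(as.vector(a2), as.vector(b2)))
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE]
  pr <- unique(pr)
  for (i in seq_len(nrow(pr))) union_(pr[i, 1], pr[i, 2])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Write / read a two-channel image as TIFF
#'
#' Each channel is written as a (multi-page, for stacks) 32-bit float TIFF;
#' pixel/voxel geometry and channel names go to a JSON sidecar
#' (`<basename>.json`).
#'
#' @param image A [two_channel_image()].
#' @param basename Path prefix; files `<basename>_small.tif`,
#'   `<basename>_long.tif` and `<basename>.json` are written.
#' @return Invisibly, the vector of files written.
#' @export
write_two_channel_tiff <- function(image, basename) {
  stopifnot(inherits(image, "two_channel_image"))
  f1 <- paste0(basename, "_small.tif")
  f2 <- paste0(basename, "_long.tif")
  fj <- paste0(basename, ".json")
  as_pages <- function(a, sc) {
    a <- a / sc
    if (length(dim(a)) == 2) list(a)
    else lapply(seq_len(dim(a)[3]), function(k) a[, , k])
  }
  # TIFF payload is stored on [0, 1]; the count scale goes to the sidecar
  sc1 <- max(1, max(image$small)); sc2 <- max(1, max(image$long))
  tiff::writeTIFF(as_pages(image$small, sc1), f1, bits.per.sample = 32L)
  tiff::writeTIFF(as_pages(image$long, sc2), f2, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_nm = image$pixel_size_nm,
                            voxel_size_nm = image$voxel_size_nm,
                            channels = image$channels,
                            dim = dim(image$small),
                            scale = c(sc1, sc2)),
                       fj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(f1, f2, fj))
}

#' @rdname write_two_channel_tiff
#' @export
read_two_channel_tiff <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  rd <- function(f, sc) {
    pages <- tiff::readTIFF(f, all = TRUE)
    a <- if (length(pages) == 1) pages[[1]]
         else array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    a * sc
  }
  two_channel_image(rd(paste0(basename, "_small.tif"), meta$scale[1]),
                    rd(paste0(basename, "_long.tif"), meta$scale[2]),
                    pixel_size_nm = meta$pixel_size_nm,
                    voxel_size_nm = meta$voxel_size_nm,
                    channels = meta$channels)
}
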