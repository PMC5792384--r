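# PET forward model ybar = A G P x: image-space Gaussian PSF (P), Siddon
# ray-traced parallel-beam projection (G), per-bin attenuation factors (A),
# count-scale calibration, phase partitioning, and Poisson noise.

#' Parallel-beam projection geometry
#'
#' @param n_angles projection angles, uniform over \[0, pi).
#' @param n_bins radial bins per angle.
#' @param bin_mm radial bin size, mm (bins are centred on the rotation
#'   axis).
#' @return list of class `"proj_geometry"`.
#' @export
proj_geometry <- function(n_angles = 180L, n_bins = 192L, bin_mm = 2) {
  structure(list(n_angles = as.integer(n_angles),
                 n_bins = as.integer(n_bins), bin_mm = bin_mm,
                 angles = (seq_len(n_angles) - 1) * pi / n_angles),
            class = "proj_geometry")
}

#' Siddon traversal of a single ray
#'
#' Exact pixel intersection lengths of the line
#' `{p : p.x cos(angle) + p.y sin(angle) = s}` with a centred square pixel
#' grid.
#'
#' @param grid_n grid size in pixels.
#' @param pixel_mm pixel size, mm.
#' @param angle ray angle, radians.
#' @param s signed radial offset of the ray from the grid centre, mm.
#' @return tibble `pixel` (linear index, column-major), `row`, `col`,
#'   `length_mm`; zero rows if the ray misses the grid.
#' @export
siddon_ray <- function(grid_n, pixel_mm, angle, s) {
  r <- cpp_siddon_ray(grid_n, grid_n, pixel_mm, angle, s)
  idx <- r$idx
  tibble::tibble(pixel = idx,
                 row = ((idx - 1) %% grid_n) + 1L,
                 col = ((idx - 1) %/% grid_n) + 1L,
                 length_mm = r$len)
}

#' Image-space PSF blurring
#'
#' Gaussian convolution with sigma = fwhm / (2 sqrt(2 log 2)); `fwhm_mm =
#' 0` is the identity. The kernel is normalized, so interior sources keep
#' their total activity.
#'
#' @param image numeric matrix.
#' @param fwhm_mm full width at half maximum of the PSF, mm.
#' @param pixel_mm pixel size, mm.
#' @return blurred matrix.
#' @export
apply_psf <- function(image, fwhm_mm = 4.5, pixel_mm = 3) {
  if (fwhm_mm < 0) rlang::abort("`fwhm_mm` must be non-negative")
  if (fwhm_mm == 0) return(image)
  sigma_px <- fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_mm
  cpp_gauss_blur(image, sigma_px)
}

#' Per-bin attenuation factors from a mu map
#'
#' `A_j = exp(-sum_ray mu * length)` using the same Siddon traversal as the
#' geometric projector.
#'
#' @param mu_map linear attenuation coefficients, 1/mm, on the image grid.
#' @param geometry a [proj_geometry()].
#' @param pixel_mm pixel size, mm.
#' @return matrix `n_bins x n_angles` of factors in (0, 1\].
#' @export
attenuation_factors <- function(mu_map, geometry, pixel_mm = 3) {
  if (any(mu_map < 0)) rlang::abort("attenuation coefficients must be non-negative")
  exp(-cpp_project(mu_map, pixel_mm, geometry$angles, geometry$n_bins,
                   geometry$bin_mm))
}

#' System operators for the forward model
#'
#' @param geometry a [proj_geometry()].
#' @param pixel_mm pixel size, mm.
#' @param fwhm_mm PSF FWHM, mm.
#' @param attenuation optional precomputed factor matrix (from
#'   [attenuation_factors()]); `NULL` means no attenuation.
#' @return list of class `"system_operators"`.
#' @export
system_operators <- function(geometry, pixel_mm = 3, fwhm_mm = 4.5,
                             attenuation = NULL) {
  structure(list(geometry = geometry, pixel_mm = pixel_mm,
                 fwhm_mm = fwhm_mm, attenuation = attenuation),
            class = "system_operators")
}

#' Forward-project an activity image
#'
#' Applies P (PSF), then G (Siddon projection), then A (attenuation); the
#' chain is linear and non-negativity preserving. Output units:
#' concentration x mm (line integrals), to be scaled by frame duration,
#' phase weight and the global count calibration by the caller.
#'
#' @param image activity concentration image (non-negative matrix).
#' @param operators a [system_operators()].
#' @return noise-free sinogram matrix `n_bins x n_angles`.
#' @export
forward_project <- function(image, operators) {
  g <- operators$geometry
  blurred <- apply_psf(image, operators$fwhm_mm, operators$pixel_mm)
  sino <- cpp_project(blurred, operators$pixel_mm, g$angles, g$n_bins, g$bin_mm)
  if (!is.null(operators$attenuation)) {
    if (!all(dim(operators$attenuation) == dim(sino)))
      rlang::abort("attenuation factor matrix does not match the geometry")
    sino <- sino * operators$attenuation
  }
  sino
}

#' Calibrate the global count scale
#'
#' Returns the factor `s` such that the total noise-free true counts in the
#' last time frame, summed over all sinogram bins and motion phases, equals
#' `target` (50,000 for a 3-mm slice by default).
#'
#' @param last_frame_sinograms list (over phases) of noise-free mean
#'   sinograms for the last frame, already weighted by frame duration and
#'   phase weight.
#' @param target target true counts in the last frame.
#' @return scalar scale factor.
#' @export
calibrate_scale <- function(last_frame_sinograms, target = 50000) {
  if (is.matrix(last_frame_sinograms))
    last_frame_sinograms <- list(last_frame_sinograms)
  tot <- sum(vapply(last_frame_sinograms, sum, numeric(1)))
  if (tot <= 0) rlang::abort("cannot calibrate: last frame has zero total counts")
  target / tot
}

#' Phase weights for partitioning a frame over motion phases
#'
#' Cardiac and respiratory cycles are short relative to the frame
#' durations, so each of the evenly divided phases receives an equal share
#' `1 / n_total` of every frame's duration.
#'
#' @param spec a [motion_phase_spec()].
#' @return tibble `phase`, `cardiac`, `resp`, `weight` (summing to 1).
#' @export
partition_frame_over_phases <- function(spec) {
  w <- spec$phases
  if (abs(sum(w$weight) - 1) > 1e-9)
    rlang::abort("internal error: phase weights do not sum to 1")
  w
}

#' Poisson noise realization of a mean sinogram
#'
#' Independent Poisson draw per bin; reproducible under a fixed seed.
#'
#' @param mean_sinogram matrix of non-negative mean counts.
#' @param seed optional integer seed (set locally).
#' @return integer-valued matrix of the same shape.
#' @export
add_poisson_noise <- function(mean_sinogram, seed = NULL) {
  if (any(mean_sinogram < 0)) rlang::abort("mean counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  matrix(rpois(length(mean_sinogram), mean_sinogram),
         nrow(mean_sinogram), ncol(mean_sinogram))
}

#' Measure the realized PSF width on a fine grid
#'
#' Applies [apply_psf()] to a single-pixel point source and measures the
#' full width at half maximum of the central profile by linear
#' interpolation of the half-maximum crossings.
#'
#' @param fwhm_mm nominal PSF FWHM, mm.
#' @param pixel_mm grid pixel size, mm (use a fine grid, <= 1 mm).
#' @param n grid size (odd, so the source sits on a pixel centre).
#' @return measured FWHM, mm.
#' @export
measure_psf_fwhm <- function(fwhm_mm = 4.5, pixel_mm = 0.5, n = 129L) {
  img <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  img[c0, c0] <- 1
  b <- apply_psf(img, fwhm_mm, pixel_mm)
  y <- b[c0, ]
  x <- (seq_len(n) - c0) * pixel_mm
  half <- max(y) / 2
  ip <- which.max(y)
  li <- max(which(y[seq_len(ip)] < half))
  ri <- ip - 1 + min(which(y[ip:n] < half))
  left <- approx(y[c(li, li + 1)], x[c(li, li + 1)], xout = half)$y
  right <- approx(y[c(ri - 1, ri)], x[c(ri - 1, ri)], xout = half)$y
  right - left
}
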