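# ROI-based evaluation: myocardium masking, per-realization ROI means,
# mean / sample-SD across noise realizations, bias relative to the static
# gold standard b = (K1_M - K1_ST)/K1_ST, "true bias" relative to the
# generating K1, and the standard-deviation reduction
# delta = |sigma_MC - sigma_GA| / sigma_GA.

#' Myocardium mask from the last-frame static image
#'
#' Pixels at or above `threshold_fraction` of the image maximum, keeping
#' the largest connected component.
#'
#' @param image non-negative image (static reconstruction of the last,
#'   4-min frame).
#' @param threshold_fraction fraction of the image maximum.
#' @return logical matrix.
#' @export
myocardium_mask <- function(image, threshold_fraction = 0.5) {
  if (threshold_fraction <= 0) return(image > 0)
  m <- image >= threshold_fraction * max(image)
  if (!any(m))
    rlang::abort("threshold produced an empty myocardium mask")
  lab <- EBImage::bwlabel(m * 1)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

new_roi <- function(pixels, name, pixel_mm, slice_mm) {
  structure(list(pixels = as.integer(pixels), name = name,
                 volume_ml = length(pixels) * pixel_mm^2 * slice_mm / 1000),
            class = "roi_spec")
}

#' Default myocardial and blood-pool ROIs
#'
#' Four ~0.18-mL myocardial ROIs (7 pixels at 3-mm pixels and slice) at
#' septal, anterior, defect-centre and inferolateral mid-wall positions,
#' each restricted to myocardium/defect pixels at least one pixel away
#' from the wall edges (4-neighbour erosion); plus a ~4-pixel LV blood-pool
#' ROI kept away from the myocardium.
#'
#' @param phantom a phantom.
#' @param n_pixels pixels per myocardial ROI.
#' @param angles_deg angular ROI positions (ROI3 is the defect centre).
#' @return named list of `roi_spec` objects (`ROI1`..`ROI4`,
#'   `blood_pool`).
#' @export
default_rois <- function(phantom, n_pixels = 7,
                         angles_deg = c(ROI1 = 195, ROI2 = 80,
                                        ROI3 = 135, ROI4 = -45)) {
  lab <- phantom$label_map
  myo <- lab == 6L | lab == 7L
  ker <- EBImage::makeBrush(3, "diamond")
  eroded <- EBImage::erode(myo * 1, ker) > 0
  xy <- grid_coords(phantom$grid_shape, phantom$pixel_size)
  hc <- phantom$lv_center_mm
  rmid <- mean(phantom$config$wall_radii)
  rois <- lapply(names(angles_deg), function(nm) {
    a <- angles_deg[[nm]] * pi / 180
    cx <- hc[1] + rmid * cos(a); cy <- hc[2] + rmid * sin(a)
    d2 <- (xy$x - cx)^2 + (xy$y - cy)^2
    cand <- which(eroded)
    pix <- cand[order(d2[cand])][seq_len(n_pixels)]
    new_roi(pix, nm, phantom$pixel_size, phantom$slice_thickness)
  })
  names(rois) <- names(angles_deg)
  rois$blood_pool <- blood_pool_roi(phantom)
  rois
}

#' LV blood-pool ROI for an image-derived input function
#'
#' @param phantom a phantom.
#' @param n_pixels ROI size (about 4 pixels).
#' @param margin_px required distance, in pixels, from any myocardium or
#'   defect pixel.
#' @return a `roi_spec`; errors if the ROI cannot keep the margin.
#' @export
blood_pool_roi <- function(phantom, n_pixels = 4, margin_px = 2) {
  lab <- phantom$label_map
  xy <- grid_coords(phantom$grid_shape, phantom$pixel_size)
  hc <- phantom$lv_center_mm
  d2 <- (xy$x - hc[1])^2 + (xy$y - hc[2])^2
  cand <- which(lab == 4L)
  pix <- cand[order(d2[cand])][seq_len(n_pixels)]
  myo_idx <- which(lab == 6L | lab == 7L)
  rc <- cbind(((pix - 1) %% nrow(lab)) + 1, ((pix - 1) %/% nrow(lab)) + 1)
  rcm <- cbind(((myo_idx - 1) %% nrow(lab)) + 1, ((myo_idx - 1) %/% nrow(lab)) + 1)
  mind <- min(sqrt(outer(rc[, 1], rcm[, 1], "-")^2 +
                   outer(rc[, 2], rcm[, 2], "-")^2))
  if (mind < margin_px)
    rlang::abort("blood-pool ROI placement touches the myocardium")
  new_roi(pix, "blood_pool", phantom$pixel_size, phantom$slice_thickness)
}

#' ROI statistics across noise realizations
#'
#' Per-realization ROI mean of the parameter map, then mean and sample
#' (N - 1) standard deviation across realizations.
#'
#' @param k1_maps list (over realizations) of parameter maps (matrices),
#'   or a single map for noise-free series.
#' @param roi a `roi_spec`.
#' @return list of class `"roi_stats"`: `means` (per realization),
#'   `mean`, `sd`, `n`.
#' @export
roi_stats <- function(k1_maps, roi) {
  if (is.matrix(k1_maps)) k1_maps <- list(k1_maps)
  means <- vapply(k1_maps, function(m) {
    v <- m[roi$pixels]
    mean(v[is.finite(v)])
  }, numeric(1))
  n <- length(means)
  structure(list(means = means, mean = mean(means),
                 sd = if (n >= 2) sd(means) else NA_real_, n = n,
                 roi = roi$name),
            class = "roi_stats")
}

#' Bias of a method relative to the static gold standard
#'
#' `b = (K1_M - K1_ST) / K1_ST` (signed fraction).
#'
#' @param method_stats,st_stats `roi_stats` objects (or numbers).
#' @return signed fractional bias.
#' @export
bias_metric <- function(method_stats, st_stats) {
  m <- if (inherits(method_stats, "roi_stats")) method_stats$mean else method_stats
  s <- if (inherits(st_stats, "roi_stats")) st_stats$mean else st_stats
  if (abs(s) < .Machine$double.eps)
    rlang::abort("static mean K1 is zero; bias undefined")
  (m - s) / s
}

#' Bias relative to the generating ground truth
#'
#' @param method_stats `roi_stats` or a number.
#' @param true_k1 the generating K1 value.
#' @return signed fraction relative to truth.
#' @export
truth_bias <- function(method_stats, true_k1) {
  m <- if (inherits(method_stats, "roi_stats")) method_stats$mean else method_stats
  if (abs(true_k1) < .Machine$double.eps)
    rlang::abort("true K1 is zero; bias undefined")
  (m - true_k1) / true_k1
}

#' Standard-deviation reduction of MC relative to GA
#'
#' `delta = |sigma_MC - sigma_GA| / sigma_GA`.
#'
#' @param mc_stats,ga_stats `roi_stats` objects (or numbers, the sigmas).
#' @return fractional reduction.
#' @export
sd_reduction <- function(mc_stats, ga_stats) {
  sm <- if (inherits(mc_stats, "roi_stats")) mc_stats$sd else mc_stats
  sg <- if (inherits(ga_stats, "roi_stats")) ga_stats$sd else ga_stats
  if (!is.finite(sg) || sg <= 0)
    rlang::abort("GA standard deviation must be positive")
  abs(sm - sg) / sg
}

#' Image-derived input function from a dynamic series
#'
#' Per-frame mean concentration over a blood-pool ROI.
#'
#' @param series list of per-frame images.
#' @param blood_roi a `roi_spec` inside the LV blood pool.
#' @param schedule a [frame_schedule()].
#' @return framed tibble `frame`, `start_s`, `dur_s`, `value`.
#' @export
image_derived_if <- function(series, blood_roi, schedule) {
  vals <- vapply(series, function(img) mean(img[blood_roi$pixels]), numeric(1))
  tibble::tibble(frame = schedule$frame, start_s = schedule$start_s,
                 dur_s = schedule$dur_s, value = vals)
}

#' Bilinear line profile through an image
#'
#' Samples at one-pixel spacing along the segment from `p0` to `p1`
#' (physical mm coordinates).
#'
#' @param image matrix.
#' @param p0,p1 endpoints, mm (`c(x, y)`).
#' @param pixel_mm pixel size, mm.
#' @return tibble `distance_mm`, `x`, `y`, `value`.
#' @export
line_profile <- function(image, p0, p1, pixel_mm = 3) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- floor(len / pixel_mm) + 1
  tfrac <- if (n == 1) 0 else seq(0, 1, length.out = n)
  x <- p0[1] + tfrac * (p1[1] - p0[1])
  y <- p0[2] + tfrac * (p1[2] - p0[2])
  shape <- dim(image)
  col <- x / pixel_mm + (shape[2] + 1) / 2
  row <- (shape[1] + 1) / 2 - y / pixel_mm
  if (any(row < 1 | row > shape[1] | col < 1 | col > shape[2]))
    rlang::abort("profile endpoints must lie inside the grid")
  r0 <- pmin(floor(row), shape[1] - 1); c0 <- pmin(floor(col), shape[2] - 1)
  fr <- row - r0; fc <- col - c0
  v <- (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
       (1 - fr) * fc * image[cbind(r0, c0 + 1)] +
       fr * (1 - fc) * image[cbind(r0 + 1, c0)] +
       fr * fc * image[cbind(r0 + 1, c0 + 1)]
  tibble::tibble(distance_mm = tfrac * len, x = x, y = y, value = v)
}

#' Apparent wall thickness on a radial profile
#'
#' Full width at half maximum across the myocardial wall, measured on a
#' radial profile from the LV centre outward at the given angle, with the
#' half level taken between the wall peak and the profile minimum inside
#' the blood pool.  Used to quantify motion blurring of the wall.
#'
#' @param image activity or K1 image.
#' @param phantom a phantom (for the LV centre).
#' @param angle_deg profile direction.
#' @param r_max_mm profile length.
#' @return FWHM in mm (NA if no clear peak).
#' @export
wall_thickness_fwhm <- function(image, phantom, angle_deg = 80,
                                r_max_mm = 45) {
  hc <- phantom$lv_center_mm
  a <- angle_deg * pi / 180
  prof <- line_profile(image, hc, hc + r_max_mm * c(cos(a), sin(a)),
                       phantom$pixel_size)
  fwhm_of_profile(prof$distance_mm, prof$value)
}

# linear-interpolated FWHM of a single-peak profile
fwhm_of_profile <- function(x, y) {
  ip <- which.max(y)
  if (ip == 1 || ip == length(y)) return(NA_real_)
  half <- (max(y) + min(y[seq_len(ip)])) / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(ip, 2)) if (y[i - 1] < half) {
    left <- approx(y[(i - 1):i], x[(i - 1):i], xout = half)$y; break
  }
  for (i in seq(ip, length(y) - 1)) if (y[i + 1] < half) {
    right <- approx(y[i:(i + 1)], x[i:(i + 1)], xout = half)$y; break
  }
  right - left
}
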