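# Multi-resolution Thirion demons deformable registration and the
# image-warping operations used for motion correction.  Fields follow the
# package's pull-back convention: warping image I with field u gives
# out(p) = I(p + u(p)); a "to_reference" field pulls a phase image into
# the reference frame, a "from_reference" field pulls the reference map
# into a phase.

#' Demons registration settings
#'
#' @param levels pyramid downsampling factors, coarse to fine.
#' @param iterations demons iterations per level.
#' @param smooth_sigma Gaussian smoothing sigma of the displacement field
#'   after each iteration, pixels (at each level).
#' @param step_cap maximum per-iteration update magnitude, pixels.
#' @return list of class `"demons_settings"`.
#' @export
demons_settings <- function(levels = c(4, 2, 1), iterations = c(100, 50, 25),
                            smooth_sigma = 1.5, step_cap = 2) {
  stopifnot(length(levels) == length(iterations))
  structure(list(levels = levels, iterations = iterations,
                 smooth_sigma = smooth_sigma, step_cap = step_cap),
            class = "demons_settings")
}

image_gradient <- function(m) {
  n <- nrow(m); p <- ncol(m)
  gr <- m; gc <- m
  gr[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  gr[1, ] <- m[2, ] - m[1, ]; gr[n, ] <- m[n, ] - m[n - 1, ]
  gc[, 2:(p - 1)] <- (m[, 3:p] - m[, 1:(p - 2)]) / 2
  gc[, 1] <- m[, 2] - m[, 1]; gc[, p] <- m[, p] - m[, p - 1]
  list(gr = gr, gc = gc)
}

downsample2 <- function(m, f) {
  if (f == 1) return(m)
  m <- cpp_gauss_blur(m, f / 2)
  n <- nrow(m) %/% f; p <- ncol(m) %/% f
  out <- matrix(0, n, p)
  for (i in seq_len(f)) for (j in seq_len(f))
    out <- out + m[seq(i, by = f, length.out = n),
                   seq(j, by = f, length.out = p)]
  out / f^2
}

upsample_field <- function(u, shape, scale) {
  # bilinear resize of a displacement component, rescaling magnitudes
  n0 <- nrow(u); p0 <- ncol(u)
  ri <- (seq_len(shape[1]) - 0.5) / shape[1] * n0 + 0.5
  ci <- (seq_len(shape[2]) - 0.5) / shape[2] * p0 + 0.5
  ri <- pmin(pmax(ri, 1), n0); ci <- pmin(pmax(ci, 1), p0)
  r0 <- pmin(floor(ri), n0 - 1); c0 <- pmin(floor(ci), p0 - 1)
  fr <- ri - r0; fc <- ci - c0
  A <- u[r0, c0]; B <- u[r0, c0 + 1]; C <- u[r0 + 1, c0]; D <- u[r0 + 1, c0 + 1]
  FR <- matrix(fr, shape[1], shape[2]); FC <- matrix(fc, shape[1], shape[2],
                                                     byrow = TRUE)
  ((1 - FR) * (1 - FC) * A + (1 - FR) * FC * B + FR * (1 - FC) * C +
      FR * FC * D) * scale
}

demons_level <- function(fixed, moving, u_r, u_c, iters, sigma, cap) {
  g <- image_gradient(fixed)
  g2 <- g$gr^2 + g$gc^2
  for (it in seq_len(iters)) {
    mw <- cpp_warp_bilinear(moving, u_r, u_c, 0)
    diff <- mw - fixed
    denom <- g2 + diff^2
    scale <- ifelse(denom > 1e-9, diff / denom, 0)
    sr <- -scale * g$gr
    sc <- -scale * g$gc
    mag <- sqrt(sr^2 + sc^2)
    over <- mag > cap
    if (any(over)) {
      sr[over] <- sr[over] * cap / mag[over]
      sc[over] <- sc[over] * cap / mag[over]
    }
    u_r <- cpp_gauss_blur(u_r + sr, sigma)
    u_c <- cpp_gauss_blur(u_c + sc, sigma)
  }
  list(u_r = u_r, u_c = u_c)
}

#' Thirion demons deformable registration
#'
#' Multi-resolution additive demons: per-iteration update proportional to
#' the intensity difference times the fixed-image gradient, normalized by
#' `|grad f|^2 + diff^2`, with Gaussian regularization of the field after
#' every iteration. Returns the field `u` such that
#' `moving(p + u(p)) ~ fixed(p)`.
#'
#' @param fixed,moving images on the same grid (non-constant).
#' @param settings a [demons_settings()].
#' @param pixel_mm pixel size, mm (fields are stored in pixels and tagged
#'   with this size).
#' @return a `motion_field` (direction unset: `"registered"`), with the
#'   final normalized cross-correlation in attribute `ncc`.
#' @export
demons_register <- function(fixed, moving, settings = demons_settings(),
                            pixel_mm = 1) {
  if (!all(dim(fixed) == dim(moving)))
    rlang::abort("fixed and moving images must share a grid")
  if (sd(fixed) < 1e-12 || sd(moving) < 1e-12)
    rlang::abort("cannot register constant images (no gradient information)")
  shape <- dim(fixed)
  u_r <- u_c <- NULL
  for (li in seq_along(settings$levels)) {
    f <- settings$levels[li]
    fl <- downsample2(fixed, f); ml <- downsample2(moving, f)
    if (is.null(u_r)) {
      u_r <- matrix(0, nrow(fl), ncol(fl)); u_c <- u_r
    } else {
      u_r <- upsample_field(u_r, dim(fl), prev_f / f)
      u_c <- upsample_field(u_c, dim(fl), prev_f / f)
    }
    lev <- demons_level(fl, ml, u_r, u_c, settings$iterations[li],
                        settings$smooth_sigma, settings$step_cap)
    u_r <- lev$u_r; u_c <- lev$u_c
    prev_f <- f
  }
  if (!all(dim(u_r) == shape)) {
    u_r <- upsample_field(u_r, shape, prev_f)
    u_c <- upsample_field(u_c, shape, prev_f)
  }
  field <- new_motion_field(u_r, u_c, pixel_mm, "registered")
  mw <- cpp_warp_bilinear(moving, u_r, u_c, 0)
  attr(field, "ncc") <- suppressWarnings(
    stats::cor(as.vector(mw), as.vector(fixed)))
  field
}

#' Estimate both field directions for every motion phase
#'
#' Registers each phase image to the reference (giving the `to_reference`
#' field used to pull phase PET images into the reference frame) and the
#' reference to each phase (the `from_reference` field used to push the
#' reference attenuation map out to the phase). The reference phase gets
#' exact zero fields; no numerical field inversion is used.
#'
#' @param mr_images list of per-phase images (e.g. `simulate_mr_study()$images`).
#' @param reference_phase index of the reference phase.
#' @param settings a [demons_settings()].
#' @param pixel_mm pixel size, mm.
#' @return list (per phase) of lists with elements `to_reference` and
#'   `from_reference`.
#' @export
estimate_all_fields <- function(mr_images, reference_phase = 1L,
                                settings = demons_settings(), pixel_mm = 1) {
  ref <- mr_images[[reference_phase]]
  lapply(seq_along(mr_images), function(p) {
    if (p == reference_phase) {
      z <- matrix(0, nrow(ref), ncol(ref))
      zf <- function(dir) new_motion_field(z, z, pixel_mm, dir, p, p)
      return(list(to_reference = zf("to_reference"),
                  from_reference = zf("from_reference")))
    }
    to_ref <- tryCatch(
      demons_register(ref, mr_images[[p]], settings, pixel_mm),
      error = function(e) rlang::abort(
        sprintf("registration failed for phase %d: %s", p, conditionMessage(e))))
    from_ref <- tryCatch(
      demons_register(mr_images[[p]], ref, settings, pixel_mm),
      error = function(e) rlang::abort(
        sprintf("registration failed for phase %d: %s", p, conditionMessage(e))))
    to_ref$direction <- "to_reference"
    to_ref$source_phase <- as.integer(p); to_ref$target_phase <- reference_phase
    from_ref$direction <- "from_reference"
    from_ref$source_phase <- reference_phase; from_ref$target_phase <- as.integer(p)
    list(to_reference = to_ref, from_reference = from_ref)
  })
}

#' Warp an image through a motion field
#'
#' Pull-back resampling: linear interpolation for continuous images,
#' nearest-neighbour for label maps; out-of-grid samples take `fill`.
#'
#' @param image matrix.
#' @param field a `motion_field` on the image grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill background value.
#' @return warped matrix.
#' @export
warp_image <- function(image, field, interpolation = c("linear", "nearest"),
                       fill = 0) {
  interpolation <- match.arg(interpolation)
  if (!all(dim(image) == dim(field$dr)))
    rlang::abort("field is not defined on the image grid")
  if (interpolation == "linear")
    cpp_warp_bilinear(image, field$dr, field$dc, fill)
  else
    cpp_warp_nearest(image, field$dr, field$dc, fill)
}

#' Transform the reference attenuation map to a motion phase
#'
#' @param reference_mu mu map in the reference phase, 1/mm.
#' @param from_reference_field a `from_reference` motion field.
#' @return mu map at the field's target phase.
#' @export
warp_attenuation_map <- function(reference_mu, from_reference_field) {
  if (from_reference_field$direction != "from_reference")
    rlang::abort("warp_attenuation_map needs a from_reference field")
  warp_image(reference_mu, from_reference_field)
}

#' Assemble a dynamic study from per-phase reconstructions
#'
#' Inputs are per-frame, per-phase reconstructions already in activity
#' concentration units. `"ST"` passes through the motionless series;
#' `"GA"` keeps the reference-phase reconstruction of each frame; `"NMC"`
#' sums phases with their weights without warping; `"MC"` warps each
#' phase's reconstruction to the reference with its `to_reference` field,
#' then sums.
#'
#' @param recons for `"ST"` a list of frame images; otherwise a list (over
#'   frames) of lists (over phases) of images.
#' @param fields per-phase field list from [estimate_all_fields()] (used
#'   by `"MC"`).
#' @param mode one of `"ST"`, `"GA"`, `"NMC"`, `"MC"`.
#' @param spec a [motion_phase_spec()].
#' @return list of per-frame images.
#' @export
assemble_study <- function(recons, fields = NULL,
                           mode = c("ST", "GA", "NMC", "MC"),
                           spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "ST") return(recons)
  stopifnot(!is.null(spec))
  w <- spec$phases$weight
  ref <- spec$reference_phase
  lapply(recons, function(frame_list) {
    missing <- which(vapply(frame_list, is.null, logical(1)))
    if (length(missing))
      rlang::abort(paste0("missing phase reconstructions: ",
                          paste(missing, collapse = ", ")))
    switch(mode,
      GA = frame_list[[ref]],
      NMC = Reduce(`+`, Map(function(img, wt) img * wt, frame_list, w)),
      MC = Reduce(`+`, Map(function(img, wt, p)
        warp_image(img, fields[[p]]$to_reference) * wt,
        frame_list, w, seq_along(frame_list))))
  })
}
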