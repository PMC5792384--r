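# Ground-truth motion model: cyclic cardiac contraction about the LV centre
# plus a superior-inferior respiratory translation of the whole thorax.
# Fields are stored as pull-back displacements: warping an image I with a
# field d gives out(p) = I(p + d(p)); the field returned by
# true_deformation() maps each motion-phase grid point back to the
# reference-phase location of the material found there ("from_reference" in
# the registration module's vocabulary).

#' Motion phase specification
#'
#' The cardiac cycle is divided evenly into `n_cardiac` phases and the
#' respiratory cycle into `n_resp` phases; every (cardiac, respiratory)
#' pair is one motion phase. Phase (1, 1) is end-diastole/end-exhalation
#' and is the motion-free reference. `"CM"` uses 10 cardiac phases (10
#' total), `"CRM"` 5 cardiac x 5 respiratory (25 total), `"ST"` a single
#' motionless phase.
#'
#' @param motion one of `"ST"`, `"CM"`, `"CRM"`.
#' @param cardiac_amplitude peak fractional radial contraction of the heart
#'   (unitless).
#' @param resp_amplitude_mm peak superior-inferior translation, mm.
#' @param n_cardiac,n_resp phase counts; defaults follow `motion`.
#' @return list of class `"motion_phase_spec"` with a `phases` tibble
#'   (columns `phase`, `cardiac`, `resp`, `weight`).
#' @export
motion_phase_spec <- function(motion = c("CRM", "CM", "ST"),
                              cardiac_amplitude = 0.15,
                              resp_amplitude_mm = 12,
                              n_cardiac = NULL, n_resp = NULL) {
  motion <- match.arg(motion)
  if (is.null(n_cardiac))
    n_cardiac <- switch(motion, ST = 1L, CM = 10L, CRM = 5L)
  if (is.null(n_resp))
    n_resp <- switch(motion, ST = 1L, CM = 1L, CRM = 5L)
  n_total <- n_cardiac * n_resp
  phases <- tidyr::expand_grid(resp = seq_len(n_resp),
                               cardiac = seq_len(n_cardiac))
  phases <- tibble::tibble(phase = seq_len(n_total),
                           cardiac = phases$cardiac, resp = phases$resp,
                           weight = 1 / n_total)
  structure(list(motion = motion, n_cardiac = n_cardiac, n_resp = n_resp,
                 n_total = n_total, reference = c(1L, 1L),
                 reference_phase = 1L,
                 cardiac_amplitude = cardiac_amplitude,
                 resp_amplitude_mm = resp_amplitude_mm,
                 phases = phases),
            class = "motion_phase_spec")
}

# raised-cosine cyclic weight, zero at phase index 1 (reference)
cycle_weight <- function(i, n) {
  if (n <= 1) return(0)
  0.5 * (1 - cos(2 * pi * (i - 1) / n))
}

new_motion_field <- function(dr, dc, pixel_mm, direction,
                             source_phase = NA_integer_,
                             target_phase = NA_integer_) {
  structure(list(dr = dr, dc = dc, pixel_mm = pixel_mm,
                 direction = direction, source_phase = source_phase,
                 target_phase = target_phase),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  mag <- sqrt(x$dr^2 + x$dc^2) * x$pixel_mm
  cat(sprintf("<motion_field> %dx%d, %s, |d| max %.2f mm mean %.2f mm\n",
              nrow(x$dr), ncol(x$dr), x$direction, max(mag), mean(mag)))
  invisible(x)
}

#' Displacement components of a motion field in mm
#'
#' @param field a `motion_field`.
#' @return list with matrices `dx` (rightward) and `dy` (upward), mm.
#' @export
field_mm <- function(field) {
  list(dx = field$dc * field$pixel_mm, dy = -field$dr * field$pixel_mm)
}

#' Ground-truth deformation of a motion phase
#'
#' Cardiac component: material at phase radius rho (from the LV centre)
#' originates at reference radius rho * (1 + a * w(c) * taper(rho)), a
#' smooth compactly-supported radial stretch whose pull-back contracts the
#' heart; w is a raised-cosine cycle weight, zero at end-diastole.
#' Respiratory component: uniform translation of amplitude
#' `resp_amplitude_mm * v(r)`, zero at end-exhalation. The resulting map is
#' checked to be invertible (positive finite-difference Jacobian).
#'
#' @param phantom a phantom.
#' @param spec a [motion_phase_spec()].
#' @param phase phase index in `spec$phases` (or a `c(cardiac, resp)` pair).
#' @return a `motion_field` (direction `"from_reference"`) whose pull-back
#'   of a reference map produces the phase map.
#' @export
true_deformation <- function(phantom, spec, phase) {
  if (length(phase) == 2L) {
    row <- which(spec$phases$cardiac == phase[1] & spec$phases$resp == phase[2])
    if (!length(row)) rlang::abort("phase index outside (n_cardiac, n_resp)")
    phase <- spec$phases$phase[row]
  }
  if (phase < 1 || phase > spec$n_total)
    rlang::abort("phase index outside (n_cardiac, n_resp)")
  ci <- spec$phases$cardiac[phase]; rsp <- spec$phases$resp[phase]
  wc <- cycle_weight(ci, spec$n_cardiac)
  wr <- cycle_weight(rsp, spec$n_resp)

  h <- phantom$pixel_size
  shape <- phantom$grid_shape
  xy <- grid_coords(shape, h)
  hc <- phantom$lv_center_mm
  ty <- -spec$resp_amplitude_mm * wr    # torso moves superiorly (+y) by A*wr

  # remove the translation, then apply the radial stretch about the LV centre
  x0 <- xy$x; y0 <- xy$y + ty
  rho <- sqrt((x0 - hc[1])^2 + (y0 - hc[2])^2)
  R1 <- 30; R2 <- 70                    # mm, taper support of cardiac motion
  tap <- ifelse(rho <= R1, 1,
                ifelse(rho >= R2, 0,
                       cos(pi * (rho - R1) / (2 * (R2 - R1)))^2))
  stretch <- 1 + spec$cardiac_amplitude * wc * tap
  xs <- hc[1] + (x0 - hc[1]) * stretch
  ys <- hc[2] + (y0 - hc[2]) * stretch

  dc <- (xs - xy$x) / h
  dr <- -(ys - xy$y) / h
  field <- new_motion_field(dr, dc, h, "from_reference",
                            source_phase = spec$reference_phase,
                            target_phase = as.integer(phase))
  jmin <- min(field_jacobian(field))
  if (jmin <= 0)
    rlang::abort(sprintf(
      "motion amplitudes produce a non-invertible deformation (min Jacobian %.3f)", jmin))
  field
}

#' Finite-difference Jacobian determinant of the field's coordinate map
#'
#' The map is p -> p + d(p) on the pixel grid; determinants are computed by
#' central differences (one-sided at the border).
#'
#' @param field a `motion_field`.
#' @return matrix of Jacobian determinants.
#' @export
field_jacobian <- function(field) {
  mr <- row(field$dr) + field$dr
  mc <- col(field$dc) + field$dc
  d_dr <- function(m) {
    out <- m
    n <- nrow(m)
    out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
    out[1, ] <- m[2, ] - m[1, ]; out[n, ] <- m[n, ] - m[n - 1, ]
    out
  }
  d_dc <- function(m) t(d_dr(t(m)))
  d_dr(mr) * d_dc(mc) - d_dc(mr) * d_dr(mc)
}

#' Warp a phantom property map through a motion field
#'
#' Pull-back (backward) warping: continuous maps use bilinear
#' interpolation, the label map nearest-neighbour; samples falling outside
#' the grid take the background (air) value.
#'
#' @param phantom a phantom.
#' @param field a `motion_field` on the phantom grid.
#' @param map_kind one of `"activity"`, `"mu"`, `"pd"`, `"t1"`, `"t2"`,
#'   `"label"`.
#' @param tissue_values named per-label activity concentrations, required
#'   for `map_kind = "activity"`.
#' @return the warped map (matrix).
#' @export
deform_maps <- function(phantom, field,
                        map_kind = c("activity", "mu", "pd", "t1", "t2", "label"),
                        tissue_values = NULL) {
  map_kind <- match.arg(map_kind)
  if (!all(dim(field$dr) == phantom$grid_shape))
    rlang::abort("field is not defined on the phantom grid")
  if (map_kind == "activity") {
    if (is.null(tissue_values))
      rlang::abort("`tissue_values` is required for map_kind = \"activity\"")
    m <- activity_map(phantom, tissue_values)
  } else m <- property_map(phantom, map_kind)
  if (map_kind == "label")
    cpp_warp_nearest(m, field$dr, field$dc, 0)
  else
    cpp_warp_bilinear(m, field$dr, field$dc, 0)
}

#' Numerically invert a motion field
#'
#' Fixed-point iteration for the inverse pull-back map; adequate for the
#' smooth, small-amplitude deformations generated here.
#'
#' @param field a `motion_field`.
#' @param iters fixed-point iterations.
#' @return the inverse `motion_field`.
#' @export
invert_field <- function(field, iters = 30) {
  dr_i <- -field$dr; dc_i <- -field$dc
  for (k in seq_len(iters)) {
    wr <- cpp_warp_bilinear(field$dr, dr_i, dc_i, 0)
    wc <- cpp_warp_bilinear(field$dc, dr_i, dc_i, 0)
    dr_i <- -wr; dc_i <- -wc
  }
  new_motion_field(dr_i, dc_i, field$pixel_mm,
                   direction = if (field$direction == "from_reference")
                     "to_reference" else "from_reference",
                   source_phase = field$target_phase,
                   target_phase = field$source_phase)
}

# residual |d + d_inv(p + d(p))| in pixels, for inversion quality checks
field_composition_residual <- function(field, inverse) {
  wr <- cpp_warp_bilinear(inverse$dr, field$dr, field$dc, 0)
  wc <- cpp_warp_bilinear(inverse$dc, field$dr, field$dc, 0)
  sqrt((field$dr + wr)^2 + (field$dc + wc)^2)
}
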