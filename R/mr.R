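# Analytic spoiled gradient-echo MR simulation.  Per motion phase the
# PD/T1/T2 maps are warped with the ground-truth deformation and converted
# to a steady-state magnitude signal
#   S = PD sin(a) (1 - E1) / (1 - cos(a) E1) * exp(-TE/T2),  E1 = exp(-TR/T1).
# MR thermal noise is deliberately absent.  T2 (not T2*) is used in the
# decay term since no T2* values are defined for the tissues.

#' Gradient-echo sequence parameters
#'
#' @param tr repetition time, ms.
#' @param te echo time, ms (`0 < te < tr`).
#' @param fa flip angle, degrees (`0 < fa < 180`).
#' @return list of class `"gre_params"`.
#' @export
gre_params <- function(tr = 9.56, te = 2.4, fa = 46) {
  if (!(te > 0 && te < tr))
    rlang::abort("gradient-echo timing requires 0 < TE < TR")
  if (!(fa > 0 && fa < 180))
    rlang::abort("flip angle must be in (0, 180) degrees")
  structure(list(tr = tr, te = te, fa = fa), class = "gre_params")
}

#' Spoiled gradient-echo steady-state signal
#'
#' Vectorized over pixels; background (`pd == 0`) gives zero signal.
#'
#' @param pd proton density (fraction of water).
#' @param t1,t2 relaxation times, ms (positive where `pd > 0`).
#' @param params a [gre_params()].
#' @return signal in arbitrary units, same shape as `pd`.
#' @export
gre_signal <- function(pd, t1, t2, params = gre_params()) {
  a <- params$fa * pi / 180
  out <- pd * 0
  act <- pd > 0
  if (any(act)) {
    e1 <- exp(-params$tr / t1[act])
    out[act] <- pd[act] * sin(a) * (1 - e1) / (1 - cos(a) * e1) *
      exp(-params$te / t2[act])
  }
  out
}

#' Simulate the MR magnitude image of one motion phase
#'
#' Warps the phantom's PD/T1/T2 maps to the phase with the ground-truth
#' deformation, evaluates the spoiled-GRE signal, and (optionally) passes
#' the image through a fully sampled forward/inverse discrete Fourier
#' transform, returning the magnitude.
#'
#' @param phantom a phantom.
#' @param spec a [motion_phase_spec()].
#' @param phase phase index.
#' @param params a [gre_params()].
#' @param kspace_roundtrip logical; include the k-space round trip.
#' @param field optional deformation to use instead of
#'   [true_deformation()].
#' @return MR magnitude image (matrix, arbitrary units).
#' @export
simulate_phase_image <- function(phantom, spec, phase, params = gre_params(),
                                 kspace_roundtrip = TRUE, field = NULL) {
  if (is.null(field)) field <- true_deformation(phantom, spec, phase)
  pd <- deform_maps(phantom, field, "pd")
  t1 <- deform_maps(phantom, field, "t1")
  t2 <- deform_maps(phantom, field, "t2")
  t1[t1 <= 0] <- 1; t2[t2 <= 0] <- 1   # background pixels; pd = 0 there
  img <- gre_signal(pd, t1, t2, params)
  if (kspace_roundtrip) {
    ksp <- fft(img)
    img <- Mod(fft(ksp, inverse = TRUE)) / length(img)
  }
  img
}

#' Simulate MR images for every motion phase of a study
#'
#' Magnitudes are normalized to a maximum of 1 across the whole study (not
#' per phase) so registration sees consistent intensities.
#'
#' @inheritParams simulate_phase_image
#' @return list of class `"mr_study"`: `images` (list over phases),
#'   `norm` (the normalization factor), `params`, `spec`.
#' @export
simulate_mr_study <- function(phantom, spec, params = gre_params(),
                              kspace_roundtrip = TRUE) {
  imgs <- lapply(seq_len(spec$n_total), function(p)
    simulate_phase_image(phantom, spec, p, params, kspace_roundtrip))
  mx <- max(vapply(imgs, max, numeric(1)))
  imgs <- lapply(imgs, function(m) m / mx)
  structure(list(images = imgs, norm = mx, params = params, spec = spec),
            class = "mr_study")
}
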