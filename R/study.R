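# End-to-end orchestration: phantom -> dynamic activity -> forward model ->
# calibration -> MR simulation -> registration -> per-realization
# reconstruction of the ST / GA / NMC / MC series -> voxelwise kinetic
# fitting -> ROI evaluation.

#' Study configuration
#'
#' Collects every tunable of the simulated experiment. Defaults reproduce
#' the package's standard study conditions: 128 x 128 grid at 3 mm, the
#' 17-frame schedule, 180 x 192 parallel-beam geometry, 4.5-mm PSF, 50,000
#' true counts in the last frame, 25 noise realizations.
#'
#' @param motion `"ST"`, `"CM"` (10 cardiac phases) or `"CRM"` (5 cardiac
#'   x 5 respiratory).
#' @param n_realizations Poisson noise realizations.
#' @param seed master seed; per-realization substreams are drawn from it.
#' @param phantom a [phantom_config()].
#' @param geometry a [proj_geometry()].
#' @param fwhm_mm PSF full width at half maximum, mm.
#' @param target_counts true counts in the last (4-min) frame.
#' @param schedule a [frame_schedule()].
#' @param aif an [input_function()].
#' @param demons a [demons_settings()].
#' @param cardiac_amplitude,resp_amplitude_mm motion amplitudes.
#' @param threshold_fraction myocardium mask threshold.
#' @param fine_dt_s kinetics fine grid step, s.
#' @param rv_lead_min RV blood curve lead, min.
#' @param use_true_fields logical; bypass MR simulation + registration and
#'   correct with the ground-truth fields (for diagnostics).
#' @return list of class `"study_config"`.
#' @export
study_config <- function(motion = "CRM", n_realizations = 25, seed = 1,
                         phantom = phantom_config(),
                         geometry = proj_geometry(),
                         fwhm_mm = 4.5, target_counts = 50000,
                         schedule = frame_schedule(),
                         aif = input_function(),
                         demons = demons_settings(),
                         cardiac_amplitude = 0.15, resp_amplitude_mm = 12,
                         threshold_fraction = 0.5, fine_dt_s = 0.1,
                         rv_lead_min = 0.1, use_true_fields = FALSE) {
  structure(as.list(environment()), class = "study_config")
}

#' Frame-averaged activity concentration per tissue
#'
#' Blood-pool tissues carry the (framed) input function (RV with its lead);
#' perfused tissues the one-tissue-compartment curve; air zero.
#'
#' @param phantom a phantom.
#' @param schedule a [frame_schedule()].
#' @param aif an [input_function()].
#' @param fine_dt_s fine grid step, s.
#' @param rv_lead_min RV lead, min.
#' @return matrix frames x tissues, columns named by tissue label.
#' @export
framed_tissue_activity <- function(phantom, schedule, aif, fine_dt_s = 0.1,
                                   rv_lead_min = 0.1) {
  bl <- blood_curves(aif, schedule, fine_dt_s, rv_lead_min)
  props <- phantom$properties
  out <- sapply(seq_len(nrow(props)), function(i) {
    p <- props[i, ]
    if (!is.na(p$blood) && p$blood == "lv") return(bl$lv$value)
    if (!is.na(p$blood) && p$blood == "rv") return(bl$rv$value)
    if (p$K1 <= 0) return(rep(0, nrow(schedule)))
    frame_average(tissue_tac(list(K1 = p$K1, k2 = p$k2), aif, fine_dt_s,
                             t_end_s = max(schedule$end_s)), schedule)$value
  })
  colnames(out) <- as.character(props$label)
  out
}

#' Simulate noise-free mean sinograms for every frame and phase
#'
#' Builds per-phase activity and attenuation maps with the ground-truth
#' deformations, applies the forward model ybar = A G P x with the true
#' phase attenuation, weights by frame duration and phase weight, and
#' calibrates the global count scale to the target last-frame total.
#'
#' @param phantom a phantom.
#' @param spec a [motion_phase_spec()].
#' @param schedule,aif,fine_dt_s,rv_lead_min kinetics inputs.
#' @param geometry a [proj_geometry()].
#' @param fwhm_mm PSF FWHM, mm.
#' @param target_counts last-frame calibration target.
#' @return list: `ybar` (list\[frame\]\[phase\] of mean-count sinograms),
#'   `scale`, `A_ref`, `A_true` (per phase), `mu_ref`, `fields_true`,
#'   `act_ref` (per-frame reference activity maps), `framed` (tissue
#'   activity matrix), `st_ybar` (motionless noise-free sinograms).
#' @export
simulate_mean_sinograms <- function(phantom, spec, schedule, aif,
                                    geometry = proj_geometry(),
                                    fwhm_mm = 4.5, target_counts = 50000,
                                    fine_dt_s = 0.1, rv_lead_min = 0.1) {
  h <- phantom$pixel_size
  framed <- framed_tissue_activity(phantom, schedule, aif, fine_dt_s,
                                   rv_lead_min)
  nf <- nrow(schedule); np <- spec$n_total
  fields_true <- lapply(seq_len(np), function(p)
    true_deformation(phantom, spec, p))
  mu_ref <- property_map(phantom, "mu")
  A_ref <- attenuation_factors(mu_ref, geometry, h)
  A_true <- lapply(seq_len(np), function(p) {
    if (p == spec$reference_phase) return(A_ref)
    mu_p <- deform_maps(phantom, fields_true[[p]], "mu")
    attenuation_factors(mu_p, geometry, h)
  })

  act_ref <- lapply(seq_len(nf), function(m)
    activity_map(phantom, framed[m, ]))
  w <- spec$phases$weight
  ybar <- vector("list", nf)
  for (m in seq_len(nf)) {
    ybar[[m]] <- vector("list", np)
    for (p in seq_len(np)) {
      act <- if (p == spec$reference_phase) act_ref[[m]] else
        cpp_warp_bilinear(act_ref[[m]], fields_true[[p]]$dr,
                          fields_true[[p]]$dc, 0)
      ops <- system_operators(geometry, h, fwhm_mm, A_true[[p]])
      ybar[[m]][[p]] <- forward_project(act, ops) * schedule$dur_s[m] * w[p]
    }
  }
  scale <- calibrate_scale(ybar[[nf]], target_counts)
  for (m in seq_len(nf)) for (p in seq_len(np))
    ybar[[m]][[p]] <- ybar[[m]][[p]] * scale

  st_ops <- system_operators(geometry, h, fwhm_mm, A_ref)
  st_ybar <- lapply(seq_len(nf), function(m)
    forward_project(act_ref[[m]], st_ops) * schedule$dur_s[m] * scale)

  list(ybar = ybar, scale = scale, A_ref = A_ref, A_true = A_true,
       mu_ref = mu_ref, fields_true = fields_true, act_ref = act_ref,
       framed = framed, st_ybar = st_ybar)
}

# reconstruct one corrected sinogram into concentration units
recon_conc <- function(y, att, geometry, grid_n, pixel_mm, denom) {
  fbp(precorrect(y, att), geometry, grid_n, pixel_mm) / denom
}

#' Run the full simulation experiment
#'
#' Executes the pipeline end to end and evaluates ST / GA / NMC / MC. With
#' `motion = "ST"` the gated and corrected studies coincide with the
#' uncorrected one (single motionless phase); with `"CM"`/`"CRM"` the MC
#' study uses Demons motion fields estimated from the simulated MR phase
#' images (or the ground-truth fields if `use_true_fields`).
#'
#' @param config a [study_config()].
#' @param outdir optional directory; when given, result tables (CSV),
#'   parameter maps (NIfTI) and a JSON manifest are written there.
#' @return object of class `"pet_mc_study"`; see [tidy.pet_mc_study()] and
#'   [glance.pet_mc_study()].
#' @export
run_study <- function(config = study_config(), outdir = NULL) {
  cfg <- config
  phantom <- build_phantom(cfg$phantom)
  spec <- motion_phase_spec(cfg$motion,
                            cardiac_amplitude = cfg$cardiac_amplitude,
                            resp_amplitude_mm = cfg$resp_amplitude_mm)
  schedule <- cfg$schedule
  geometry <- cfg$geometry
  h <- phantom$pixel_size
  grid_n <- phantom$grid_shape[1]
  nf <- nrow(schedule); np <- spec$n_total
  ref <- spec$reference_phase
  w <- spec$phases$weight

  sim <- simulate_mean_sinograms(phantom, spec, schedule, cfg$aif, geometry,
                                 cfg$fwhm_mm, cfg$target_counts,
                                 cfg$fine_dt_s, cfg$rv_lead_min)

  # motion fields for correction: estimated from MR, or ground truth
  if (np > 1) {
    if (cfg$use_true_fields) {
      fields <- lapply(seq_len(np), function(p) {
        fr <- sim$fields_true[[p]]
        list(to_reference = invert_field(fr), from_reference = fr)
      })
    } else {
      mr <- simulate_mr_study(phantom, spec)
      fields <- estimate_all_fields(mr$images, ref, cfg$demons, h)
    }
    A_warp <- lapply(seq_len(np), function(p) {
      if (p == ref) return(sim$A_ref)
      mu_p <- warp_attenuation_map(sim$mu_ref, fields[[p]]$from_reference)
      attenuation_factors(mu_p, geometry, h)
    })
  } else {
    fields <- list(NULL)
    A_warp <- list(sim$A_ref)
  }

  # static (motionless, noise-free) reference series
  st_series <- lapply(seq_len(nf), function(m)
    recon_conc(sim$st_ybar[[m]], sim$A_ref, geometry, grid_n, h,
               sim$scale * schedule$dur_s[m]))

  mask <- myocardium_mask(st_series[[nf]], cfg$threshold_fraction)
  mask_idx <- which(mask)
  basis <- kinetic_basis(cfg$aif, schedule, fine_dt_s = cfg$fine_dt_s,
                         rv_lead_min = cfg$rv_lead_min)

  extract_Y <- function(series) vapply(series, function(img) img[mask_idx],
                                       numeric(length(mask_idx)))
  st_fit <- fit_k1_map(t(extract_Y(st_series)), basis)

  # per-realization reconstruction and fitting
  set.seed(cfg$seed)
  rseeds <- sample.int(.Machine$integer.max - 1L, cfg$n_realizations)
  studies <- c("GA", "NMC", "MC")
  fits <- setNames(lapply(studies, function(s) vector("list",
                                                      cfg$n_realizations)),
                   studies)
  example_series <- NULL
  last_frame_images <- list(NMC = vector("list", cfg$n_realizations),
                            MC = vector("list", cfg$n_realizations))
  for (r in seq_len(cfg$n_realizations)) {
    set.seed(rseeds[r])
    ga <- vector("list", nf); nmc <- vector("list", nf); mc <- vector("list", nf)
    for (m in seq_len(nf)) {
      denom <- sim$scale * schedule$dur_s[m]
      ysum <- NULL; mc_img <- NULL
      for (p in seq_len(np)) {
        y <- add_poisson_noise(sim$ybar[[m]][[p]])
        ysum <- if (is.null(ysum)) y else ysum + y
        img_p <- recon_conc(y, A_warp[[p]], geometry, grid_n, h, denom)
        if (np > 1) img_p <- warp_image(img_p, fields[[p]]$to_reference)
        mc_img <- if (is.null(mc_img)) img_p else mc_img + img_p
        if (p == ref)
          ga[[m]] <- recon_conc(y, sim$A_ref, geometry, grid_n, h,
                                denom * w[ref])
      }
      nmc[[m]] <- recon_conc(ysum, sim$A_ref, geometry, grid_n, h, denom)
      mc[[m]] <- mc_img
    }
    fits$GA[[r]] <- fit_k1_map(t(extract_Y(ga)), basis)
    fits$NMC[[r]] <- fit_k1_map(t(extract_Y(nmc)), basis)
    fits$MC[[r]] <- fit_k1_map(t(extract_Y(mc)), basis)
    if (r == 1L)
      example_series <- list(GA = ga, NMC = nmc, MC = mc)
    last_frame_images$NMC[[r]] <- nmc[[nf]]
    last_frame_images$MC[[r]] <- mc[[nf]]
  }

  k1_map_of <- function(fit) {
    m <- matrix(NA_real_, grid_n, grid_n)
    m[mask_idx] <- fit$K1
    m
  }
  k1_maps <- lapply(fits, function(fr) lapply(fr, k1_map_of))
  st_k1_map <- k1_map_of(st_fit)

  true_k1_map <- activity_map(phantom, setNames(phantom$properties$K1,
                                                phantom$properties$label))
  rois <- default_rois(phantom)

  out <- structure(list(config = cfg, phantom = phantom, spec = spec,
                        schedule = schedule, basis = basis,
                        scale = sim$scale, mask = mask,
                        mask_idx = mask_idx, rois = rois,
                        st_series = st_series, st_k1_map = st_k1_map,
                        st_fit = st_fit, fits = fits, k1_maps = k1_maps,
                        true_k1_map = true_k1_map,
                        example_series = example_series,
                        last_frame_images = last_frame_images,
                        fields = if (np > 1) fields else NULL,
                        sim = sim),
                   class = "pet_mc_study")
  out$roi_summary <- summarize_rois(out)
  out$manifest <- list(
    package = "petmcsim",
    version = as.character(utils::packageVersion("petmcsim")),
    motion = cfg$motion, n_phases = np, n_frames = nf,
    n_realizations = cfg$n_realizations, seed = cfg$seed,
    scale = sim$scale, config_hash = rlang::hash(cfg[setdiff(names(cfg),
                                                             c("aif"))]))
  if (!is.null(outdir)) write_study_outputs(out, outdir)
  out
}

#' ROI summary table of a study
#'
#' One row per (study, ROI): mean and SD of the ROI-mean K1 across
#' realizations, bias relative to ST, bias relative to the generating
#' truth, and (relative to GA) the standard-deviation reduction.
#'
#' @param study a `pet_mc_study`.
#' @return tibble.
#' @export
summarize_rois <- function(study) {
  myo_rois <- study$rois[c("ROI1", "ROI2", "ROI3", "ROI4")]
  st_stats <- lapply(myo_rois, function(roi) roi_stats(study$st_k1_map, roi))
  rows <- list()
  for (s in c("ST", names(study$fits))) {
    maps <- if (s == "ST") list(study$st_k1_map) else study$k1_maps[[s]]
    for (rn in names(myo_rois)) {
      roi <- myo_rois[[rn]]
      rs <- roi_stats(maps, roi)
      truth <- mean(study$true_k1_map[roi$pixels])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        study = s, roi = rn, n = rs$n, mean_K1 = rs$mean, sd_K1 = rs$sd,
        bias_vs_ST = bias_metric(rs, st_stats[[rn]]),
        truth_bias = truth_bias(rs, truth))
    }
  }
  out <- dplyr::bind_rows(rows)
  ga_sd <- out$sd_K1[out$study == "GA"]
  out$sd_reduction_vs_GA <- NA_real_
  for (s in c("NMC", "MC")) {
    i <- out$study == s
    out$sd_reduction_vs_GA[i] <- abs(out$sd_K1[i] - ga_sd) / ga_sd
  }
  out
}

#' Defect contrast of each study
#'
#' Mean healthy-ROI K1 (ROI1, ROI2, ROI4) minus defect-ROI K1 (ROI3),
#' averaged across realizations.
#'
#' @param study a `pet_mc_study`.
#' @return named numeric vector over studies.
#' @export
defect_contrast <- function(study) {
  s <- study$roi_summary
  vapply(unique(s$study), function(st) {
    m <- s[s$study == st, ]
    mean(m$mean_K1[m$roi != "ROI3"]) - m$mean_K1[m$roi == "ROI3"]
  }, numeric(1))
}

#' @export
print.pet_mc_study <- function(x, ...) {
  cat(sprintf("<pet_mc_study> motion=%s phases=%d realizations=%d mask=%d px\n",
              x$config$motion, x$spec$n_total, x$config$n_realizations,
              length(x$mask_idx)))
  print(x$roi_summary, n = Inf)
  invisible(x)
}

#' @rdname run_study
#' @param x a `pet_mc_study`.
#' @param ... unused.
#' @export
tidy.pet_mc_study <- function(x, ...) x$roi_summary

#' @rdname run_study
#' @export
glance.pet_mc_study <- function(x, ...) {
  dc <- defect_contrast(x)
  tibble::tibble(motion = x$config$motion, n_phases = x$spec$n_total,
                 n_realizations = x$config$n_realizations,
                 mask_pixels = length(x$mask_idx), scale = x$scale,
                 contrast_NMC = unname(dc["NMC"]),
                 contrast_MC = unname(dc["MC"]))
}

#' Read a study configuration from a YAML or JSON file
#'
#' Scalar fields of [study_config()] (motion, n_realizations, seed,
#' fwhm_mm, target_counts, amplitudes, threshold_fraction, ...) can be
#' given in a plain config file; unknown keys are rejected with their
#' path. Structured arguments (phantom, geometry, schedule, aif, demons)
#' keep their defaults unless given as nested blocks of the matching
#' constructor's arguments.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      rlang::abort("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  builders <- list(phantom = phantom_config, geometry = proj_geometry,
                   schedule = frame_schedule, aif = input_function,
                   demons = demons_settings)
  allowed <- names(formals(study_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    rlang::abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  args <- list()
  for (k in names(raw)) {
    args[[k]] <- if (k %in% names(builders))
      do.call(builders[[k]], as.list(raw[[k]])) else raw[[k]]
  }
  do.call(study_config, args)
}
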