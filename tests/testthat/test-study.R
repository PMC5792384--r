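test_that("a static end-to-end run recovers healthy perfusion within 10%", {
  st <- fx_st_study()
  expect_equal(st$spec$n_total, 1L)
  # noise-free static fit: healthy-region (mid-wall ROI average) K1 near
  # the generating 0.80; individual ROIs lose a little more to partial
  # volume at 3-mm pixels
  s <- st$roi_summary
  healthy <- s[s$study == "ST" & s$roi != "ROI3", ]
  expect_lt(abs(mean(healthy$mean_K1) / 0.80 - 1), 0.10)
  expect_true(all(abs(healthy$mean_K1 / 0.80 - 1) < 0.15))
  # the defect ROI sits well below the healthy ones
  def <- s$mean_K1[s$study == "ST" & s$roi == "ROI3"]
  expect_lt(def, min(healthy$mean_K1))
  # without motion the three noisy studies coincide realization by
  # realization (single phase, zero fields)
  for (r in 1:2) {
    expect_equal(st$fits$NMC[[r]]$K1, st$fits$MC[[r]]$K1, tolerance = 1e-8)
    expect_equal(st$fits$NMC[[r]]$K1, st$fits$GA[[r]]$K1, tolerance = 1e-8)
  }
})

test_that("the manifest traces the run configuration", {
  st <- fx_st_study()
  expect_equal(st$manifest$motion, "ST")
  expect_equal(st$manifest$n_phases, 1)
  expect_equal(st$manifest$n_realizations, 2)
  expect_match(st$manifest$config_hash, "^[0-9a-f]+$")
  expect_equal(motion_phase_spec("CM")$n_total, 10L)
})

test_that("noise realizations are reproducible from the master seed", {
  cfg <- study_config(motion = "ST", n_realizations = 3, seed = 42)
  set.seed(cfg$seed)
  a <- sample.int(.Machine$integer.max - 1L, 3)
  set.seed(cfg$seed)
  b <- sample.int(.Machine$integer.max - 1L, 3)
  expect_identical(a, b)
  m <- matrix(runif(300, 0, 8), 30, 10)
  expect_identical(add_poisson_noise(m, seed = a[1]),
                   add_poisson_noise(m, seed = a[1]))
})

test_that("tidy and glance expose the study summaries", {
  st <- fx_st_study()
  td <- tidy(st)
  expect_true(all(c("study", "roi", "mean_K1", "sd_K1", "bias_vs_ST",
                    "truth_bias") %in% names(td)))
  expect_equal(nrow(td), 16)   # 4 studies x 4 ROIs
  gl <- glance(st)
  expect_equal(gl$mask_pixels, length(st$mask_idx))
  expect_s3_class(autoplot(st), "ggplot")
  expect_s3_class(plot_roi_summary(st), "ggplot")
})

test_that("gated reconstructions use the reference-phase count share", {
  crm <- fx_crm_study()
  spec <- crm$spec
  # duration share is exact; realized counts differ only through the
  # phase-dependent deformation and attenuation of the activity
  expect_equal(spec$phases$weight[spec$reference_phase], 1 / spec$n_total)
  tot <- 0; ref_tot <- 0
  for (m in 1:17) {
    tot <- tot + sum(vapply(crm$sim$ybar[[m]], sum, numeric(1)))
    ref_tot <- ref_tot + sum(crm$sim$ybar[[m]][[spec$reference_phase]])
  }
  expect_equal(ref_tot / tot, 1 / spec$n_total, tolerance = 0.05)
})

test_that("motion blurs the apparent wall and correction restores it", {
  crm <- fx_crm_study()
  sch <- crm$schedule
  g <- crm$config$geometry
  h <- crm$phantom$pixel_size
  n <- crm$phantom$grid_shape[1]
  m <- 17L
  den <- crm$scale * sch$dur_s[m]
  ysum <- Reduce(`+`, crm$sim$ybar[[m]])
  nmc <- fbp(precorrect(ysum, crm$sim$A_ref), g, n, h) / den
  mc <- Reduce(`+`, lapply(seq_len(crm$spec$n_total), function(p) {
    img <- fbp(precorrect(crm$sim$ybar[[m]][[p]], crm$sim$A_ref), g, n, h) / den
    warp_image(img, crm$fields[[p]]$to_reference)
  }))
  st_img <- crm$st_series[[m]]
  w_nmc <- wall_thickness_fwhm(nmc, crm$phantom)
  w_mc <- wall_thickness_fwhm(mc, crm$phantom)
  w_st <- wall_thickness_fwhm(st_img, crm$phantom)
  expect_gt(w_nmc, w_mc)
  expect_gte(w_mc, w_st * 0.95)
})

test_that("corrected and uncorrected images share a noise level; the K1 gap is a fit effect", {
  crm <- fx_crm_study()
  # per-voxel SD over realizations of the last-frame image, in a uniform
  # tissue region (liver): correction must not use more data than NMC
  liver <- which(crm$phantom$label_map == 3L)[1:40]
  vox_sd <- function(imgs) {
    arr <- vapply(imgs, function(i) i[liver], numeric(length(liver)))
    mean(apply(arr, 1, sd))
  }
  sd_nmc <- vox_sd(crm$last_frame_images$NMC)
  sd_mc <- vox_sd(crm$last_frame_images$MC)
  expect_lt(abs(sd_mc / sd_nmc - 1), 0.20)
  # and in the myocardium itself
  myo <- which(crm$phantom$label_map == 6L)
  vox_sd2 <- function(imgs) {
    arr <- vapply(imgs, function(i) i[myo], numeric(length(myo)))
    mean(apply(arr, 1, sd))
  }
  expect_lt(abs(vox_sd2(crm$last_frame_images$MC) /
                vox_sd2(crm$last_frame_images$NMC) - 1), 0.20)
})
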