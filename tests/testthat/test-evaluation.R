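test_that("the myocardium mask is thresholded, connected and validated", {
  st <- fx_st_study()
  img <- st$st_series[[17]]
  full <- myocardium_mask(img, 0)
  expect_equal(full, img > 0)
  m <- myocardium_mask(img, 0.5)
  truth <- st$phantom$label_map %in% c(6L, 7L)
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gt(dice, 0.8)
  expect_error(myocardium_mask(img, 1 + 1e-6), "empty")
  # single connected component
  expect_equal(max(EBImage::bwlabel(m * 1)), 1)
})

test_that("myocardial ROIs have the nominal volume away from wall edges", {
  ph <- fx_phantom()
  rois <- default_rois(ph)
  myo <- (ph$label_map == 6L | ph$label_map == 7L) * 1
  eroded <- EBImage::erode(myo, EBImage::makeBrush(3, "diamond")) > 0
  for (rn in c("ROI1", "ROI2", "ROI3", "ROI4")) {
    roi <- rois[[rn]]
    expect_lt(abs(roi$volume_ml - 0.18) / 0.18, 0.15)
    expect_true(all(eroded[roi$pixels]))
  }
  expect_true(all(ph$label_map[rois$blood_pool$pixels] == 4L))
  # defect ROI actually samples the defect
  expect_gt(sum(ph$label_map[rois$ROI3$pixels] == 7L), 0)
})

test_that("ROI statistics implement the N-1 sample formulas", {
  roi <- petmcsim:::new_roi(1:4, "test", 3, 3)
  maps3 <- lapply(c(0.8, 0.8, 0.8), function(v) matrix(v, 2, 2))
  s <- roi_stats(maps3, roi)
  expect_equal(s$mean, 0.8); expect_equal(s$sd, 0)
  maps2 <- lapply(c(0.7, 0.9), function(v) matrix(v, 2, 2))
  s2 <- roi_stats(maps2, roi)
  expect_equal(s2$mean, 0.8)
  expect_equal(s2$sd, sqrt(sum((c(0.7, 0.9) - 0.8)^2) / 1))
  # sampling behaviour of the sd estimator: s^2 ~ sigma^2 chi2_{24} / 24
  set.seed(10)
  vals <- rnorm(25, 0.8, 0.05)
  mapsN <- lapply(vals, function(v) matrix(v, 2, 2))
  sN <- roi_stats(mapsN, roi)
  ci <- 0.05 * sqrt(qchisq(c(0.001, 0.999), 24) / 24)
  expect_gt(sN$sd, ci[1]); expect_lt(sN$sd, ci[2])
})

test_that("bias and sd-reduction metrics compute their defining ratios", {
  expect_equal(bias_metric(0.9, 0.8), 0.125)
  expect_equal(bias_metric(0.8, 0.8), 0)
  expect_equal(truth_bias(0.72, 0.80), -0.10)
  expect_error(bias_metric(1, 0), "zero")
  expect_equal(sd_reduction(0.02, 0.10), 0.8)
  expect_equal(sd_reduction(0.1, 0.1), 0)
  expect_equal(sd_reduction(0, 0.1), 1)
  expect_error(sd_reduction(0.1, 0), "positive")
})

test_that("the image-derived input function tracks the true one on static data", {
  st <- fx_st_study()
  idif <- image_derived_if(st$st_series, st$rois$blood_pool, st$schedule)
  truth <- st$basis$lv
  rel <- abs(idif$value - truth$value) / max(truth$value)
  expect_lt(max(rel[-1]), 0.05)
  zero <- image_derived_if(lapply(1:17, function(i) matrix(0, 4, 4)),
                           petmcsim:::new_roi(1:4, "z", 3, 3), st$schedule)
  expect_true(all(zero$value == 0))
})

test_that("line profiles sample bilinearly with the right length", {
  img <- matrix(4.2, 64, 64)
  pr <- line_profile(img, c(-30, 0), c(30, 0), 3)
  expect_true(all(pr$value == 4.2))
  expect_equal(nrow(pr), floor(60 / 3) + 1)
  expect_error(line_profile(img, c(-500, 0), c(0, 0), 3), "inside")
  # profile across the defect on the true K1 map bottoms out at 0.36
  ph <- fx_phantom()
  k1_true <- activity_map(ph, setNames(ph$properties$K1,
                                       ph$properties$label))
  a <- ph$config$defect_angle_deg * pi / 180
  hc <- ph$lv_center_mm
  rmid <- ph$config$wall_radii[2] - ph$config$defect_thickness_mm / 2
  centre <- hc + rmid * c(cos(a), sin(a))
  along <- c(-sin(a), cos(a))
  # the chord through the defect dips well below the healthy wall value
  pr2 <- line_profile(k1_true, centre - 6 * along, centre + 6 * along,
                      ph$pixel_size)
  expect_lt(min(pr2$value), 0.5)
  # sampled exactly at defect pixel centres, the profile reads the defect
  # K1 of 0.36 (bilinear interpolation is exact on pixel centres)
  didx <- which(ph$label_map == 7L)
  rc <- cbind(((didx - 1) %% 128) + 1, ((didx - 1) %/% 128) + 1)
  d2 <- as.matrix(dist(rc)); diag(d2) <- Inf
  pair <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  p0 <- petmcsim:::rc_to_phys(rc[pair[1], 1], rc[pair[1], 2], c(128, 128),
                              ph$pixel_size)
  p1 <- petmcsim:::rc_to_phys(rc[pair[2], 1], rc[pair[2], 2], c(128, 128),
                              ph$pixel_size)
  pr_def <- line_profile(k1_true, p0, p1, ph$pixel_size)
  expect_equal(min(pr_def$value), 0.36, tolerance = 1e-9)
  expect_equal(pr_def$value[1], 0.36, tolerance = 1e-9)
  # healthy mid-wall far from the defect reads the healthy value
  healthy_pt <- hc + mean(ph$config$wall_radii) * c(cos(-a), sin(-a))
  pr3 <- line_profile(k1_true, healthy_pt, healthy_pt + c(1e-6, 0),
                      ph$pixel_size)
  expect_equal(pr3$value[1], 0.80, tolerance = 1e-9)
})

test_that("relative IDIF error under motion is worst without correction", {
  crm <- fx_crm_study()
  truth <- crm$basis$lv
  sch <- crm$schedule
  g <- crm$config$geometry
  h <- crm$phantom$pixel_size
  n <- crm$phantom$grid_shape[1]
  # noise-free NMC and MC series assembled from the mean sinograms
  nmc <- mc <- vector("list", 17)
  for (m in 1:17) {
    den <- crm$scale * sch$dur_s[m]
    ysum <- Reduce(`+`, crm$sim$ybar[[m]])
    nmc[[m]] <- fbp(precorrect(ysum, crm$sim$A_ref), g, n, h) / den
    mc[[m]] <- Reduce(`+`, lapply(seq_len(crm$spec$n_total), function(p) {
      img <- fbp(precorrect(crm$sim$ybar[[m]][[p]], crm$sim$A_ref), g, n, h) / den
      warp_image(img, crm$fields[[p]]$to_reference)
    }))
  }
  err_of <- function(series) {
    v <- image_derived_if(series, crm$rois$blood_pool, sch)$value
    max(abs(v - truth$value)[-1] / max(truth$value))
  }
  e_st <- err_of(crm$st_series)
  e_nmc <- err_of(nmc)
  e_mc <- err_of(mc)
  expect_gt(e_nmc, e_st)
  expect_gt(e_nmc, e_mc)
})
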