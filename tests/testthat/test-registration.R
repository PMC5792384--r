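make_blob <- function(n = 64, cx = 0, cy = 0, w = 8) {
  xy <- petmcsim:::grid_coords(c(n, n), 1)
  exp(-((xy$x - cx)^2 + (xy$y - cy)^2) / (2 * w^2))
}

test_that("registering an image to itself yields a negligible field", {
  b <- make_blob()
  f <- demons_register(b, b)
  expect_lt(max(sqrt(f$dr^2 + f$dc^2)), 0.05)
})

test_that("a known 2-pixel shift is recovered within 0.3 pixel", {
  fixed <- make_blob(cx = 0)
  moving <- make_blob(cx = 2)   # shifted +2 px in x
  f <- demons_register(fixed, moving)
  core <- fixed > 0.2
  expect_lt(abs(mean(f$dc[core]) - 2), 0.3)
  expect_lt(abs(mean(f$dr[core])), 0.3)
})

test_that("a smooth 5% radial contraction registers to NCC > 0.99", {
  n <- 64
  xy <- petmcsim:::grid_coords(c(n, n), 1)
  r <- sqrt(xy$x^2 + xy$y^2)
  fixed <- exp(-(r - 12)^2 / 18) + 0.5 * exp(-r^2 / 40)
  # moving: same pattern contracted by 5% (sample at r / 0.95)
  rs <- r / 0.95
  moving <- exp(-(rs - 12)^2 / 18) + 0.5 * exp(-rs^2 / 40)
  f <- demons_register(fixed, moving)
  expect_gt(attr(f, "ncc"), 0.99)
})

test_that("constant images are rejected", {
  c1 <- matrix(1, 32, 32)
  expect_error(demons_register(c1, c1), "constant")
})

test_that("estimated fields reproduce the ground-truth deformation", {
  ph <- fx_phantom()
  spec <- motion_phase_spec("CM")
  mr <- simulate_mr_study(ph, spec)
  flds <- estimate_all_fields(mr$images, 1, pixel_mm = ph$pixel_size)
  # reference phase: exact zeros
  expect_true(all(flds[[1]]$to_reference$dr == 0))
  expect_true(all(flds[[1]]$from_reference$dc == 0))
  body <- ph$label_map > 0
  for (p in c(4L, 6L)) {
    ft <- true_deformation(ph, spec, p)
    fe <- flds[[p]]$from_reference
    epe <- sqrt((ft$dr - fe$dr)^2 + (ft$dc - fe$dc)^2)
    expect_lt(mean(epe[body]), 1)
    # composing the two directions is near-identity
    res <- petmcsim:::field_composition_residual(fe, flds[[p]]$to_reference)
    expect_lt(mean(res[body]), 0.5)
  }
})

test_that("warping honours identity, exact integer shifts and round trips", {
  set.seed(4)
  img <- apply_psf(matrix(runif(64 * 64), 64, 64), 3, 1)
  z <- matrix(0, 64, 64)
  idf <- petmcsim:::new_motion_field(z, z, 1, "to_reference")
  expect_equal(warp_image(img, idf), img)
  sh <- petmcsim:::new_motion_field(z, z + 3, 1, "to_reference")
  w <- warp_image(img, sh)
  expect_equal(w[, 1:61], img[, 4:64], tolerance = 1e-12)
  # warp then inverse-warp a smooth image
  ph <- fx_phantom()
  f <- true_deformation(ph, motion_phase_spec("CRM"), 13)
  fi <- invert_field(f)
  smooth <- apply_psf(activity_map(ph, c(`1` = 1, `3` = 3, `4` = 6, `6` = 8)),
                      15, 3)
  back <- warp_image(warp_image(smooth, f), fi)
  interior <- ph$label_map > 0
  expect_lt(sqrt(mean((back - smooth)[interior]^2)) / mean(smooth[interior]),
            0.02)
})

test_that("attenuation maps are transported with the right field direction", {
  ph <- fx_phantom()
  spec <- motion_phase_spec("CRM")
  mu <- property_map(ph, "mu")
  mr <- simulate_mr_study(ph, spec)
  flds <- estimate_all_fields(mr$images, 1, pixel_mm = ph$pixel_size)
  p <- 13L   # mid systole / mid inhale
  expect_error(warp_attenuation_map(mu, flds[[p]]$to_reference),
               "from_reference")
  warped <- warp_attenuation_map(mu, flds[[p]]$from_reference)
  true_mu <- deform_maps(ph, true_deformation(ph, spec, p), "mu")
  body <- true_mu > 0
  expect_lt(sqrt(mean((warped - true_mu)[body]^2)) / mean(true_mu[body]), 0.10)
  # interpolation never creates values outside the original support
  expect_lte(max(warped), max(mu) + 1e-12)
  expect_gte(min(warped), 0)
})

test_that("study assembly obeys its zero-motion identities", {
  spec1 <- motion_phase_spec("ST")
  set.seed(9)
  frames <- lapply(1:3, function(m) matrix(runif(16), 4, 4))
  expect_identical(assemble_study(frames, mode = "ST"), frames)
  # fake a 5-phase spec where every phase saw the same image
  spec5 <- motion_phase_spec("CM", n_cardiac = 5L)
  per_phase <- lapply(frames, function(f) replicate(5, f, simplify = FALSE))
  z <- matrix(0, 4, 4)
  zf <- list(to_reference = petmcsim:::new_motion_field(z, z, 1, "to_reference"))
  fields <- replicate(5, zf, simplify = FALSE)
  ga <- assemble_study(per_phase, fields, "GA", spec5)
  nmc <- assemble_study(per_phase, fields, "NMC", spec5)
  mc <- assemble_study(per_phase, fields, "MC", spec5)
  for (m in 1:3) {
    expect_equal(mc[[m]], nmc[[m]], tolerance = 1e-12)
    expect_equal(ga[[m]], nmc[[m]], tolerance = 1e-12)
    expect_equal(nmc[[m]], frames[[m]], tolerance = 1e-12)
  }
  broken <- per_phase
  broken[[2]][3] <- list(NULL)
  expect_error(assemble_study(broken, fields, "NMC", spec5), "missing")
})
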