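test_that("Siddon traversal reproduces axis-aligned and diagonal chords", {
  r <- siddon_ray(3, 1, 0, 0)          # vertical ray through the centre
  expect_equal(nrow(r), 3)
  expect_equal(r$length_mm, rep(1, 3))
  expect_true(all(r$col == 2))
  d <- siddon_ray(1, 1, pi / 4, 0)     # diagonal through one pixel
  expect_equal(d$length_mm, sqrt(2), tolerance = 1e-9)
  miss <- siddon_ray(3, 1, 0, 10)
  expect_equal(nrow(miss), 0)
})

test_that("Siddon line integrals match dense sampling on random rays", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  for (k in 1:5) {
    ang <- runif(1, 0, pi); s <- runif(1, -40, 40)
    rr <- siddon_ray(64, 2, ang, s)
    val <- sum(img[cbind(rr$row, rr$col)] * rr$length_mm)
    tt <- seq(-120, 120, by = 0.01)
    px <- s * cos(ang) - tt * sin(ang); py <- s * sin(ang) + tt * cos(ang)
    col <- floor(px / 2 + 32) + 1; row <- floor(32 - py / 2) + 1
    ok <- col >= 1 & col <= 64 & row >= 1 & row <= 64
    dense <- sum(img[cbind(row[ok], col[ok])]) * 0.01
    expect_lt(abs(val - dense) / dense, 1e-3)
  }
  # lengths sum to the chord through the bounding box
  rr <- siddon_ray(64, 2, 0.3, 10)
  expect_gt(sum(rr$length_mm), 0)
})

test_that("PSF blurring is the identity at zero width and mass preserving", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(apply_psf(img, 0, 3), img)
  pt <- matrix(0, 41, 41); pt[21, 21] <- 7
  b <- apply_psf(pt, 4.5, 3)
  expect_equal(sum(b), 7, tolerance = 1e-3)
  u <- matrix(1, 41, 41)
  bu <- apply_psf(u, 4.5, 3)
  expect_lt(max(abs(bu[10:30, 10:30] - 1)), 1e-3)
})

test_that("the realized PSF profile has a 4.5-mm FWHM", {
  expect_equal(measure_psf_fwhm(4.5, 0.5), 4.5, tolerance = 0.1)
})

test_that("attenuation factors follow the Beer-Lambert closed form", {
  g <- proj_geometry(4, 32, 2)
  mu0 <- matrix(0, 32, 32)
  expect_true(all(attenuation_factors(mu0, g, 2) == 1))
  mu <- matrix(0.01, 32, 32)
  A <- attenuation_factors(mu, g, 2)
  # central vertical ray crosses the full 64-mm grid height
  centre_bin <- which.min(abs((seq_len(32) - 16.5) * 2))
  expect_equal(A[centre_bin, 1], exp(-0.01 * 64), tolerance = 1e-9)
  # monotone in a global mu scale
  ph <- fx_phantom()
  gg <- proj_geometry()
  mu_ph <- property_map(ph, "mu")
  A1 <- attenuation_factors(mu_ph, gg, 3)
  A2 <- attenuation_factors(2 * mu_ph, gg, 3)
  expect_true(all(A1 > 0 & A1 <= 1))
  expect_true(all(A2 <= A1 + 1e-12))
  expect_error(attenuation_factors(-mu, g, 2), "non-negative")
})

test_that("the forward chain is linear and conserves projection sums", {
  g <- proj_geometry(36, 96, 2)
  ops <- system_operators(g, 1.5, 0, NULL)
  z <- forward_project(matrix(0, 96, 96), ops)
  expect_true(all(z == 0))
  set.seed(8)
  a <- matrix(runif(96 * 96), 96, 96); b <- matrix(runif(96 * 96), 96, 96)
  expect_equal(forward_project(a + b, ops),
               forward_project(a, ops) + forward_project(b, ops),
               tolerance = 1e-12)
  # interior point source: per-angle totals constant within 1% once the
  # radial sampling is fine relative to the pixel
  gf <- proj_geometry(36, 1024, 0.25)
  pt <- matrix(0, 64, 64); pt[30, 40] <- 1
  sp <- forward_project(pt, system_operators(gf, 4, 0, NULL))
  tot <- colSums(sp)
  expect_lt(diff(range(tot)) / mean(tot), 0.01)
})

test_that("count calibration hits the target exactly and scales uniformly", {
  s1 <- matrix(2, 10, 10); s2 <- matrix(3, 10, 10)   # total 500
  sc <- calibrate_scale(list(s1, s2), target = 50000)
  expect_equal(sc, 100)
  expect_equal(sum(s1 * sc) + sum(s2 * sc), 50000)
  expect_equal(calibrate_scale(matrix(50000 / 100, 10, 10)), 1)
  earlier <- matrix(7, 10, 10)
  expect_equal(sum(earlier * sc), sum(earlier) * sc)
  expect_error(calibrate_scale(matrix(0, 2, 2)), "zero")
})

test_that("phase partitioning weights are equal shares summing to one", {
  cm <- partition_frame_over_phases(motion_phase_spec("CM"))
  expect_equal(cm$weight, rep(0.10, 10))
  crm <- partition_frame_over_phases(motion_phase_spec("CRM"))
  expect_equal(crm$weight, rep(0.04, 25))
  st <- partition_frame_over_phases(motion_phase_spec("ST"))
  expect_equal(st$weight, 1)
})

test_that("Poisson noise is seeded, mean-preserving and zero on zero means", {
  expect_true(all(add_poisson_noise(matrix(0, 20, 20)) == 0))
  m <- matrix(50, 250, 400)
  y <- add_poisson_noise(m, seed = 123)
  y2 <- add_poisson_noise(m, seed = 123)
  expect_identical(y, y2)
  expect_lt(abs(mean(y) - 50), 3 * sqrt(50 / length(m)))
  # bin-wise expectation over many realizations of a small sinogram
  mm <- matrix(c(0.5, 2, 10, 40), 2, 2)
  set.seed(77)
  acc <- matrix(0, 2, 2); acc2 <- matrix(0, 2, 2)
  n <- 300
  for (i in 1:n) { r <- add_poisson_noise(mm); acc <- acc + r; acc2 <- acc2 + r^2 }
  z <- (acc / n - mm) / sqrt(mm / n)
  expect_true(all(abs(z) < 4))
})
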