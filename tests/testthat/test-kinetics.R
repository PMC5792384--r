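test_that("parametric input functions start at zero and stay non-negative", {
  for (aif in list(input_function("feng"), input_function("biexponential"))) {
    expect_equal(eval_input_function(aif, 0), 0)
    t <- seq(0, 20, by = 0.01)
    expect_true(all(eval_input_function(aif, t) >= -1e-12))
  }
  expect_error(eval_input_function(input_function(), -0.1), "non-negative")
})

test_that("the bolus model evaluates its closed form", {
  aif <- input_function("biexponential", list(A = 1, a = 1))
  expect_equal(eval_input_function(aif, 1), exp(-1))
})

test_that("default input-function peak matches a dense grid search", {
  aif <- fx_aif()
  t <- seq(0, 9, by = 0.01)
  cp <- eval_input_function(aif, t)
  t_peak <- t[which.max(cp)]
  # an independent optimizer must agree with the dense grid
  opt <- optimize(function(u) -eval_input_function(aif, u), c(0, 9))
  expect_equal(t_peak, opt$minimum, tolerance = 0.011)
  expect_equal(max(cp), -opt$objective, tolerance = 1e-4)
})

test_that("tissue TAC scales linearly and vanishes for K1 = 0", {
  aif <- fx_aif()
  z <- tissue_tac(list(K1 = 0, k2 = 0.3), aif, 0.5, 60)
  expect_true(all(z$value == 0))
  t1 <- tissue_tac(list(K1 = 0.4, k2 = 0.2), aif, 0.5, 60)
  t2 <- tissue_tac(list(K1 = 0.8, k2 = 0.2), aif, 0.5, 60)
  expect_equal(t2$value, 2 * t1$value, tolerance = 1e-12)
})

test_that("exponential-input convolution matches its closed form", {
  t <- seq(0, 520, by = 0.1) / 60
  a <- 1.3; k2 <- 0.2; K1 <- 0.5
  aif <- input_function("tabulated", list(time = t, conc = exp(-a * t)))
  tac <- tissue_tac(list(K1 = K1, k2 = k2), aif, 0.1, 520)
  closed <- K1 * (exp(-k2 * t) - exp(-a * t)) / (a - k2)
  expect_lt(max(abs(tac$value - closed)) / max(closed), 1e-3)
})

test_that("healthy-myocardium TAC agrees with a direct trapezoid oracle", {
  aif <- fx_aif()
  tac <- tissue_tac(list(K1 = 0.80, k2 = 0.17), aif, 0.1, 520)
  # brute-force trapezoid convolution at dt/10 on a handful of times
  dt <- 0.01 / 60
  tg <- seq(0, 520 / 60, by = dt)
  cp <- eval_input_function(aif, tg)
  for (t_chk in c(0.5, 2, 5, 8.5)) {
    n <- round(t_chk / 60 / dt) * 0 + which.min(abs(tg - t_chk))
    integ <- cp[1:n] * exp(-0.17 * (tg[n] - tg[1:n]))
    oracle <- 0.80 * (sum(integ) - (integ[1] + integ[n]) / 2) * dt
    got <- tac$value[which.min(abs(tac$time_min - t_chk))]
    expect_lt(abs(got - oracle) / oracle, 0.002)
  }
})

test_that("frame averaging reproduces constants, midpoints and analytic integrals", {
  sch <- fx_schedule()
  t <- seq(0, 520, by = 0.1) / 60
  const <- tibble::tibble(time_min = t, value = rep(3.7, length(t)))
  expect_equal(frame_average(const, sch)$value, rep(3.7, 17))
  lin <- tibble::tibble(time_min = t, value = 2 * t)
  fa <- frame_average(lin, sch)
  expect_equal(fa$value, 2 * (sch$start_s + sch$dur_s / 2) / 60,
               tolerance = 1e-9)
  # analytic frame integrals of the closed-form exponential-input TAC
  a <- 1.3; k2 <- 0.2; K1 <- 0.5
  aif <- input_function("tabulated", list(time = t, conc = exp(-a * t)))
  tac <- tissue_tac(list(K1 = K1, k2 = k2), aif, 0.1, 520)
  fa2 <- frame_average(tac, sch)
  Fint <- function(u) K1 / (a - k2) * ((1 - exp(-k2 * u)) / k2 -
                                       (1 - exp(-a * u)) / a)
  analytic <- (Fint(sch$end_s / 60) - Fint(sch$start_s / 60)) /
    (sch$dur_s / 60)
  expect_lt(max(abs(fa2$value - analytic) / max(analytic)), 0.002)
  expect_error(frame_average(tibble::tibble(time_min = t[t < 4], value = 1),
                             sch), "beyond")
})

test_that("the spillover model honours its limiting cases", {
  aif <- fx_aif(); sch <- fx_schedule(); basis <- fx_basis()
  lv <- basis$lv; rv <- basis$rv
  pure_blood <- measurement_model(c(K1 = 0.8, k2 = 0.17, f_lv = 1, f_rv = 0),
                                  aif, lv, rv, sch)
  expect_equal(pure_blood$value, lv$value)
  none <- measurement_model(c(K1 = 0.8, k2 = 0.17, f_lv = 0, f_rv = 0),
                            aif, lv, rv, sch)
  tis <- frame_average(tissue_tac(c(K1 = 0.8, k2 = 0.17), aif), sch)
  expect_equal(none$value, tis$value)
  # convex combination of identical constants is the constant
  cst <- tibble::tibble(frame = sch$frame, start_s = sch$start_s,
                        dur_s = sch$dur_s, value = rep(5, 17))
  t <- seq(0, 520, by = 0.1) / 60
  aifc <- input_function("tabulated", list(time = t, conc = rep(5, length(t))))
  out <- measurement_model(c(K1 = 0, k2 = 0, f_lv = 0.3, f_rv = 0.2),
                           aifc, cst, cst, sch)
  expect_equal(out$value, rep(0.5 * 5, 17))  # (1-f)*0 + f*5 with f = 0.5
  expect_error(measurement_model(c(K1 = 1, k2 = 1, f_lv = 0.7, f_rv = 0.5),
                                 aif, lv, rv, sch), "f_lv")
})
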