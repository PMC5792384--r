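# One-tissue compartment kinetics: arterial input function, tissue
# time-activity curves Ct(t) = K1 * Cp(t) (x) exp(-k2 t), frame averaging,
# and the LV/RV spillover measurement model
#   C_PET(t_m) = f_LV C_LV(t_m) + f_RV C_RV(t_m)
#              + (1 - f_LV - f_RV) * (1/dt_m) int_{dt_m} Ct(tau) dtau.
# Time is minutes inside kinetic equations and seconds in frame schedules;
# activity concentration is in arbitrary kBq/mL-like units.

#' Arterial input function
#'
#' Parametric models for the arterial tracer concentration Cp(t):
#' * `"feng"`: Cp(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) +
#'   A3 exp(-l3 t); the default coefficients give a bolus peaking near
#'   0.6 min with a slowly decaying tail.
#' * `"biexponential"`: a gamma-variate-like bolus Cp(t) = A t exp(-a t).
#' * `"tabulated"`: linear interpolation of `params$time` (min) /
#'   `params$conc`, 0 outside the table's left edge.
#'
#' @param model model name.
#' @param params named list of coefficients (see above); defaults supplied
#'   for the parametric models.
#' @return object of class `"input_function"`.
#' @export
input_function <- function(model = c("feng", "biexponential", "tabulated"),
                           params = NULL) {
  model <- match.arg(model)
  params <- params %||% switch(model,
    feng = list(A1 = 300, l1 = 2.0, A2 = 20, l2 = 0.12, A3 = 21, l3 = 0.01),
    biexponential = list(A = 100, a = 2.0),
    tabulated = rlang::abort("tabulated model needs `params$time` and `params$conc`"))
  f <- switch(model,
    feng = function(t) {
      with(params, (A1 * t - A2 - A3) * exp(-l1 * t) +
                   A2 * exp(-l2 * t) + A3 * exp(-l3 * t))
    },
    biexponential = function(t) with(params, A * t * exp(-a * t)),
    tabulated = {
      fa <- approxfun(params$time, params$conc, rule = 2, yleft = 0)
      function(t) fa(t)
    })
  structure(list(model = model, params = params, fun = f),
            class = "input_function")
}

#' Evaluate an input function at times t (minutes)
#'
#' @param aif an [input_function()].
#' @param t times in minutes, all `>= 0`.
#' @return Cp(t), same length as `t`.
#' @export
eval_input_function <- function(aif, t) {
  if (any(t < 0)) rlang::abort("input function times must be non-negative")
  aif$fun(t)
}

#' Dynamic frame schedule
#'
#' Default: 8 x 5 s, 4 x 10 s, 2 x 20 s, 1 x 40 s, 1 x 120 s, 1 x 240 s
#' (17 contiguous frames, 520 s).
#'
#' @param durations_s frame durations in seconds.
#' @return tibble with columns `frame`, `start_s`, `dur_s`, `end_s`,
#'   `mid_min`.
#' @export
frame_schedule <- function(durations_s = c(rep(5, 8), rep(10, 4),
                                           rep(20, 2), 40, 120, 240)) {
  if (any(durations_s <= 0)) rlang::abort("frame durations must be positive")
  ends <- cumsum(durations_s)
  tibble::tibble(frame = seq_along(durations_s),
                 start_s = c(0, ends[-length(ends)]),
                 dur_s = durations_s, end_s = ends,
                 mid_min = (c(0, ends[-length(ends)]) + durations_s / 2) / 60)
}

#' Tissue time-activity curve on a fine time grid
#'
#' Evaluates Ct(t) = K1 * Cp(t) (x) exp(-k2 t) by an exponential-kernel
#' recursion equivalent to trapezoidal quadrature of the convolution
#' integral on steps of `fine_dt_s`.
#'
#' @param params list or vector with `K1` (mL/min/mL) and `k2` (1/min).
#' @param aif an [input_function()].
#' @param fine_dt_s fine grid step, seconds (must be `<= 1`).
#' @param t_end_s end of the grid, seconds.
#' @return tibble `time_min`, `value`.
#' @export
tissue_tac <- function(params, aif, fine_dt_s = 0.1, t_end_s = 520) {
  if (fine_dt_s > 1) rlang::abort("`fine_dt_s` must be <= 1 s")
  K1 <- params[["K1"]]; k2 <- params[["k2"]]
  t_min <- seq(0, t_end_s, by = fine_dt_s) / 60
  cp <- eval_input_function(aif, t_min)
  tibble::tibble(time_min = t_min,
                 value = K1 * conv_exp(cp, k2, fine_dt_s / 60))
}

# trapezoidal convolution of `x` with exp(-k2 t) on a uniform grid (dt min)
# via the recursion y[i] = E y[i-1] + dt/2 (x[i] + E x[i-1]), E = exp(-k2 dt)
conv_exp <- function(x, k2, dt_min) {
  E <- exp(-k2 * dt_min)
  n <- length(x)
  b <- c(0, dt_min / 2 * (x[-1] + E * x[-n]))
  as.numeric(stats::filter(b, E, method = "recursive"))
}

#' Frame-average a fine-grid TAC over a schedule
#'
#' Per-frame mean (1/dt_m) int_{dt_m} C(tau) dtau via cumulative
#' trapezoidal integration of the fine grid.
#'
#' @param tac tibble `time_min`, `value` (uniform fine grid).
#' @param schedule a [frame_schedule()].
#' @return tibble `frame`, `start_s`, `dur_s`, `value`.
#' @export
frame_average <- function(tac, schedule) {
  t_s <- tac$time_min * 60
  if (max(schedule$end_s) > max(t_s) + 1e-9)
    rlang::abort("frame schedule extends beyond the fine time grid")
  v <- tac$value
  n <- length(v)
  cum <- c(0, cumsum((v[-1] + v[-n]) / 2 * diff(t_s)))
  cum_at <- approxfun(t_s, cum)
  tibble::tibble(frame = schedule$frame, start_s = schedule$start_s,
                 dur_s = schedule$dur_s,
                 value = (cum_at(schedule$end_s) - cum_at(schedule$start_s)) /
                         schedule$dur_s)
}

#' Spillover measurement model for a myocardial voxel
#'
#' @param params list/vector with `K1`, `k2`, `f_lv`, `f_rv`
#'   (`f_lv + f_rv <= 1`, all non-negative).
#' @param aif an [input_function()].
#' @param lv_tac,rv_tac framed blood-pool TACs (tibbles as returned by
#'   [frame_average()], aligned with `schedule`).
#' @param schedule a [frame_schedule()].
#' @param fine_dt_s fine grid step for the tissue curve, seconds.
#' @return tibble `frame`, `start_s`, `dur_s`, `value` of C_PET.
#' @export
measurement_model <- function(params, aif, lv_tac, rv_tac, schedule,
                              fine_dt_s = 0.1) {
  f_lv <- params[["f_lv"]]; f_rv <- params[["f_rv"]]
  if (f_lv < 0 || f_rv < 0 || f_lv + f_rv > 1)
    rlang::abort("spillover fractions must be non-negative with f_lv + f_rv <= 1")
  tis <- frame_average(tissue_tac(params, aif, fine_dt_s,
                                  t_end_s = max(schedule$end_s)), schedule)
  out <- tis
  out$value <- f_lv * lv_tac$value + f_rv * rv_tac$value +
    (1 - f_lv - f_rv) * tis$value
  out
}

#' Framed blood-pool curves from the input function
#'
#' LV blood carries Cp itself; RV blood the input function advanced by
#' `rv_lead_min` (the right ventricle precedes the left).
#'
#' @param aif an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param fine_dt_s fine grid step, seconds.
#' @param rv_lead_min RV lead time, minutes.
#' @return list with framed tibbles `lv` and `rv`.
#' @export
blood_curves <- function(aif, schedule, fine_dt_s = 0.1, rv_lead_min = 0.1) {
  t_end <- max(schedule$end_s)
  t_min <- seq(0, t_end, by = fine_dt_s) / 60
  lv <- tibble::tibble(time_min = t_min, value = eval_input_function(aif, t_min))
  rv <- tibble::tibble(time_min = t_min,
                       value = eval_input_function(aif, t_min + rv_lead_min))
  list(lv = frame_average(lv, schedule), rv = frame_average(rv, schedule))
}
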