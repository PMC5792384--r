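# Unweighted least-squares estimation of (K1, k2, f_lv, f_rv) per voxel.
#
# The measurement model is linear in beta = (f_lv, f_rv, (1-f_lv-f_rv)*K1)
# once k2 is fixed: C = beta1 C_LV + beta2 C_RV + beta3 B(k2), where B(k2)
# is the frame-averaged unit-K1 tissue curve.  The map fitter profiles the
# k2 nonlinearity on a log grid with parabolic refinement and solves the
# three linear coefficients under the constraints beta1, beta2, beta3 >= 0,
# beta1 + beta2 <= 1 (tiny active-set enumeration).  fit_voxel() optionally
# polishes the profiled solution with bounded nlminb on the full nonlinear
# cost; both routes minimize the identical unweighted residual sum of
# squares.

default_k2_grid <- function() exp(seq(log(0.02), log(3), length.out = 50))

#' Precompute the fitting basis for a schedule and input function
#'
#' @param aif an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param k2_grid candidate washout rates, 1/min.
#' @param fine_dt_s fine grid step, seconds.
#' @param rv_lead_min RV lead used for the RV blood curve, minutes.
#' @return list of class `"kinetic_basis"`: framed `lv`/`rv` curves, the
#'   frames-by-k2 basis matrix `B`, `k2_grid`, and a closure `bcol(k2)`
#'   producing the basis column for any k2.
#' @export
kinetic_basis <- function(aif, schedule, k2_grid = default_k2_grid(),
                          fine_dt_s = 0.1, rv_lead_min = 0.1) {
  t_end <- max(schedule$end_s)
  t_min <- seq(0, t_end, by = fine_dt_s) / 60
  cp <- eval_input_function(aif, t_min)
  bl <- blood_curves(aif, schedule, fine_dt_s, rv_lead_min)
  bcol <- function(k2) {
    frame_average(tibble::tibble(time_min = t_min,
                                 value = conv_exp(cp, k2, fine_dt_s / 60)),
                  schedule)$value
  }
  B <- vapply(k2_grid, bcol, numeric(nrow(schedule)))
  structure(list(lv = bl$lv, rv = bl$rv, B = B, k2_grid = k2_grid,
                 bcol = bcol, schedule = schedule, aif = aif,
                 fine_dt_s = fine_dt_s, rv_lead_min = rv_lead_min),
            class = "kinetic_basis")
}

# equality-constrained least squares via the KKT system
eq_lsq <- function(X, y, C = NULL, d = NULL) {
  p <- ncol(X)
  if (is.null(C)) {
    return(tryCatch(qr.solve(X, y), error = function(e) rep(NA_real_, p)))
  }
  m <- nrow(C)
  K <- rbind(cbind(crossprod(X), t(C)), cbind(C, matrix(0, m, m)))
  rhs <- c(crossprod(X, y), d)
  sol <- tryCatch(solve(K, rhs), error = function(e) rep(NA_real_, p + m))
  sol[seq_len(p)]
}

# minimize ||X beta - y|| s.t. beta1,beta2,beta3 >= 0, beta1 + beta2 <= 1,
# by enumerating active sets (3 unknowns, 4 inequality constraints)
solve_mix <- function(X, y) {
  feasible <- function(b) !anyNA(b) && all(b >= -1e-9) && b[1] + b[2] <= 1 + 1e-9
  best <- NULL; best_rss <- Inf
  cons <- list(NULL,
               rbind(c(1, 0, 0)), rbind(c(0, 1, 0)), rbind(c(0, 0, 1)),
               rbind(c(1, 1, 0)),
               rbind(c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 0, 0), c(0, 0, 1)),
               rbind(c(0, 1, 0), c(0, 0, 1)), rbind(c(1, 1, 0), c(0, 0, 1)),
               rbind(c(1, 0, 0), c(1, 1, 0)), rbind(c(0, 1, 0), c(1, 1, 0)),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  dval <- function(C) apply(C, 1, function(r) if (all(r == c(1, 1, 0))) 1 else 0)
  for (C in cons) {
    b <- if (is.null(C)) eq_lsq(X, y) else eq_lsq(X, y, C, dval(C))
    if (!feasible(b)) next
    b <- pmax(b, 0)
    rss <- sum((X %*% b - y)^2)
    if (rss < best_rss - 1e-12) { best <- b; best_rss <- rss }
  }
  list(beta = best, rss = best_rss)
}

# re-solve with the uptake cap active: beta3 = k1_max * (1 - beta1 - beta2),
# enumerating the remaining face combinations
solve_mix_capped <- function(X, y, k1_max = 5) {
  cap <- c(k1_max, k1_max, 1)
  feasible <- function(b) !anyNA(b) && all(b >= -1e-9) &&
    b[1] + b[2] <= 1 + 1e-9
  best <- NULL; best_rss <- Inf
  extra <- list(NULL, rbind(c(1, 0, 0)), rbind(c(0, 1, 0)),
                rbind(c(1, 1, 0)), rbind(c(1, 0, 0), c(0, 1, 0)))
  dmap <- function(C) apply(C, 1, function(r) if (all(r == c(1, 1, 0))) 1 else 0)
  for (C in extra) {
    Cc <- rbind(cap, C); dd <- c(k1_max, if (is.null(C)) NULL else dmap(C))
    b <- eq_lsq(X, y, Cc, dd)
    if (!feasible(b)) next
    b <- pmax(b, 0)
    rss <- sum((X %*% b - y)^2)
    if (rss < best_rss - 1e-12) { best <- b; best_rss <- rss }
  }
  if (is.null(best)) { best <- c(0, 0, 0); best_rss <- sum(y^2) }
  list(beta = best, rss = best_rss)
}

beta_to_params <- function(beta, k2) {
  if (is.null(beta) || anyNA(beta))
    return(c(K1 = NA_real_, k2 = k2, f_lv = NA_real_, f_rv = NA_real_))
  beta <- unname(as.numeric(beta))
  f_lv <- beta[1]; f_rv <- beta[2]
  denom <- 1 - f_lv - f_rv
  K1 <- if (denom > 1e-6) beta[3] / denom else 0
  c(K1 = K1, k2 = k2, f_lv = f_lv, f_rv = f_rv)
}

#' Fit K1 maps for a matrix of measured voxel TACs
#'
#' Profiles k2 over the basis grid with one parabolic refinement step and
#' solves the constrained linear coefficients per voxel; this is the exact
#' minimizer of the unweighted least-squares cost up to the k2 grid
#' refinement.
#'
#' @param Y numeric matrix, frames x voxels, of measured framed TACs.
#' @param basis a [kinetic_basis()].
#' @param refine logical; parabolic refinement of k2 between grid points.
#' @param k1_max upper bound on K1 (mL/min/mL); voxels whose unconstrained
#'   profile solution exceeds it are re-solved with the cap active and
#'   flagged `"k1_bound"`.
#' @return tibble with one row per voxel: `voxel`, `K1`, `k2`, `f_lv`,
#'   `f_rv`, `rss`, `flag` (`"ok"`, `"zero_tac"`, `"blood_like"`,
#'   `"k1_bound"`, or `"failed"`).
#' @export
fit_k1_map <- function(Y, basis, refine = TRUE, k1_max = 5) {
  Y <- as.matrix(Y)
  nf <- nrow(Y); nv <- ncol(Y)
  kg <- basis$k2_grid; nk <- length(kg)
  CLV <- basis$lv$value; CRV <- basis$rv$value

  rss <- matrix(Inf, nk, nv)
  betas <- array(NA_real_, c(3, nk, nv))
  for (j in seq_len(nk)) {
    X <- cbind(CLV, CRV, basis$B[, j])
    bu <- qr.solve(X, Y)                      # unconstrained, all voxels
    ok <- bu[1, ] >= 0 & bu[2, ] >= 0 & bu[3, ] >= 0 & (bu[1, ] + bu[2, ]) <= 1
    res <- Y - X %*% bu
    rss[j, ok] <- colSums(res[, ok, drop = FALSE]^2)
    betas[, j, ok] <- bu[, ok]
    for (v in which(!ok)) {                   # constrained fallback
      s <- solve_mix(X, Y[, v])
      rss[j, v] <- s$rss
      betas[, j, v] <- s$beta
    }
  }

  out <- vector("list", nv)
  for (v in seq_len(nv)) {
    if (all(abs(Y[, v]) < 1e-12)) {
      out[[v]] <- tibble::tibble(voxel = v, K1 = 0, k2 = 0, f_lv = 0,
                                 f_rv = 0, rss = 0, flag = "zero_tac")
      next
    }
    j <- which.min(rss[, v])
    k2 <- kg[j]; beta <- betas[, j, v]; r <- rss[j, v]
    if (refine && j > 1 && j < nk) {
      lk <- log(kg[(j - 1):(j + 1)]); rv3 <- rss[(j - 1):(j + 1), v]
      den <- (rv3[1] - 2 * rv3[2] + rv3[3])
      if (is.finite(den) && den > 0) {
        lk_star <- lk[2] - 0.5 * (lk[3] - lk[1]) / 2 * (rv3[3] - rv3[1]) / den
        k2_star <- exp(max(min(lk_star, lk[3]), lk[1]))
        X <- cbind(CLV, CRV, basis$bcol(k2_star))
        s <- solve_mix(X, Y[, v])
        if (s$rss < r) { k2 <- k2_star; beta <- s$beta; r <- s$rss }
      }
    }
    p <- beta_to_params(beta, k2)
    flag <- if (!is.finite(p[["K1"]])) "failed"
            else if (1 - p[["f_lv"]] - p[["f_rv"]] <= 1e-6) "blood_like" else "ok"
    if (is.finite(p[["K1"]]) && p[["K1"]] > k1_max) {
      X <- cbind(CLV, CRV, basis$bcol(k2))
      s <- solve_mix_capped(X, Y[, v], k1_max)
      r <- s$rss
      p <- beta_to_params(s$beta, k2)
      p[["K1"]] <- min(p[["K1"]], k1_max)
      flag <- "k1_bound"
    }
    out[[v]] <- tibble::tibble(voxel = v, K1 = p[["K1"]], k2 = p[["k2"]],
                               f_lv = p[["f_lv"]], f_rv = p[["f_rv"]],
                               rss = r, flag = flag)
  }
  dplyr::bind_rows(out)
}

#' Fit kinetic parameters for a single measured voxel TAC
#'
#' Bounded nonlinear least squares on the full (K1, k2, f_lv, f_rv) cost:
#' the constrained basis-profile solution seeds `nlminb` (box bounds
#' K1, k2 in \[0, 5\], f in \[0, 1\]; f_lv + f_rv <= 1 enforced by
#' penalty).  Spillover fractions can be fixed via `fix`.
#'
#' @param tac_measured framed TAC: a tibble with a `value` column or a
#'   numeric vector of per-frame values.
#' @param aif an [input_function()].
#' @param lv_tac,rv_tac framed blood curves (default: derived from `aif`).
#' @param schedule a [frame_schedule()].
#' @param init named start values `K1`, `k2`, `f_lv`, `f_rv`.
#' @param bounds list with `lower`/`upper` named vectors.
#' @param fix optional named vector of parameters to hold fixed, e.g.
#'   `c(f_lv = 0, f_rv = 0)`.
#' @param basis optional precomputed [kinetic_basis()].
#' @param fine_dt_s fine grid step, seconds.
#' @return object of class `"voxel_fit"`: estimates, `rss`, `convergence`
#'   flag, and the model curve at the optimum.
#' @export
fit_voxel <- function(tac_measured, aif, lv_tac = NULL, rv_tac = NULL,
                      schedule = frame_schedule(),
                      init = c(K1 = 0.5, k2 = 0.2, f_lv = 0.1, f_rv = 0.05),
                      bounds = list(lower = c(K1 = 0, k2 = 0, f_lv = 0, f_rv = 0),
                                    upper = c(K1 = 5, k2 = 5, f_lv = 1, f_rv = 1)),
                      fix = NULL, basis = NULL, fine_dt_s = 0.1) {
  y <- if (is.data.frame(tac_measured)) tac_measured$value else as.numeric(tac_measured)
  if (nrow(schedule) < 5)
    rlang::abort("at least 5 frames are required to fit 4 parameters")
  if (length(y) != nrow(schedule))
    rlang::abort("measured TAC length does not match the frame schedule")

  if (is.null(basis))
    basis <- kinetic_basis(aif, schedule, fine_dt_s = fine_dt_s)
  if (is.null(lv_tac)) lv_tac <- basis$lv
  if (is.null(rv_tac)) rv_tac <- basis$rv
  CLV <- lv_tac$value; CRV <- rv_tac$value

  if (all(abs(y) < 1e-12)) {
    est <- c(K1 = 0, k2 = 0, f_lv = 0, f_rv = 0)
    return(structure(list(params = est, rss = 0, convergence = "zero_tac",
                          fitted = y * 0, schedule = schedule),
                     class = "voxel_fit"))
  }

  pn <- c("K1", "k2", "f_lv", "f_rv")
  fixed <- setNames(rep(NA_real_, 4), pn)
  if (!is.null(fix)) fixed[names(fix)] <- fix
  free <- is.na(fixed)

  model <- function(par) {
    p <- fixed; p[free] <- par
    tis <- basis$bcol(p[["k2"]]) * p[["K1"]]
    p[["f_lv"]] * CLV + p[["f_rv"]] * CRV +
      (1 - p[["f_lv"]] - p[["f_rv"]]) * tis
  }
  obj <- function(par) {
    p <- fixed; p[free] <- par
    pen <- max(0, p[["f_lv"]] + p[["f_rv"]] - 1)
    sum((model(par) - y)^2) + 1e6 * pen^2
  }

  # seed from the profiled linear solution (respecting fixed spillovers)
  seed <- init
  if (is.null(fix) || !all(c("f_lv", "f_rv") %in% names(fix))) {
    prof <- fit_k1_map(matrix(y, ncol = 1), basis, refine = TRUE)
    if (prof$flag[1] == "ok")
      seed <- c(K1 = prof$K1[1], k2 = prof$k2[1],
                f_lv = prof$f_lv[1], f_rv = prof$f_rv[1])
  }
  start <- pmin(pmax(seed[pn][free], bounds$lower[pn][free] + 1e-9),
                bounds$upper[pn][free])
  opt <- nlminb(start, obj, lower = bounds$lower[pn][free],
                upper = bounds$upper[pn][free],
                control = list(abs.tol = 1e-10, rel.tol = 1e-10,
                               iter.max = 500, eval.max = 1000))
  est <- fixed; est[free] <- opt$par
  structure(list(params = est, rss = sum((model(opt$par) - y)^2),
                 convergence = if (opt$convergence == 0) "ok" else "not_converged",
                 fitted = model(opt$par), measured = y, schedule = schedule),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("<voxel_fit> K1=%.4f k2=%.4f f_lv=%.3f f_rv=%.3f rss=%.4g (%s)\n",
              x$params[["K1"]], x$params[["k2"]], x$params[["f_lv"]],
              x$params[["f_rv"]], x$rss, x$convergence))
  invisible(x)
}

#' @rdname fit_voxel
#' @param x a `voxel_fit`.
#' @param ... unused.
#' @export
tidy.voxel_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = as.numeric(x$params))
}

#' @rdname fit_voxel
#' @export
glance.voxel_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_frames = length(x$fitted),
                 convergence = x$convergence)
}
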