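#' BOLD signal model exponents
#'
#' Flow-volume coupling exponent `alpha` and field-strength exponent `beta`
#' of the calibrated-BOLD signal equation. Defaults alpha = 0.18, beta = 1.5
#' are the values in common use for dual-calibrated studies at 3 T; both are
#' recorded in all provenance output.
#'
#' @param alpha flow-volume coupling exponent, in (0, 1).
#' @param beta field-strength exponent, >= 1.
#' @return An object of class `bold_model`.
#' @export
bold_model <- function(alpha = 0.18, beta = 1.5) {
  if (alpha <= 0 || alpha >= 1)
    stop_quo2("bold_model: alpha must be in (0, 1)")
  if (beta < 1) stop_quo2("bold_model: beta must be >= 1")
  structure(list(alpha = alpha, beta = beta), class = "bold_model")
}

#' Epoch observation for the calibration model
#'
#' One respiratory epoch's inputs: fractional BOLD change `b`, CBF ratio `f`,
#' and the arterial O2 contents during the epoch and at baseline.
#'
#' @param b fractional BOLD change (dimensionless).
#' @param f CBF ratio relative to baseline (> 0).
#' @param cao2,cao2_0 arterial O2 content during the epoch / at baseline,
#'   ml O2/ml blood.
#' @return An object of class `epoch_obs`.
#' @seealso [obs_from_gas()] to build the contents from end-tidal O2.
#' @export
epoch_obs <- function(b, f, cao2, cao2_0) {
  check_number(b, "b")
  check_number(f, "f", lower = 1e-12)
  check_number(cao2, "cao2", lower = 1e-12)
  check_number(cao2_0, "cao2_0", lower = 1e-12)
  structure(list(b = b, f = f, cao2 = cao2, cao2_0 = cao2_0),
            class = "epoch_obs")
}

#' Epoch observation from end-tidal O2 values
#'
#' @inheritParams epoch_obs
#' @param eto2,eto2_0 end-tidal O2 during the epoch / at baseline, mmHg
#'   (used as PaO2 surrogates).
#' @param blood a [blood_model()].
#' @return An `epoch_obs`.
#' @export
obs_from_gas <- function(b, f, eto2, eto2_0, blood = blood_model()) {
  epoch_obs(b, f, arterial_o2_content(eto2, blood),
            arterial_o2_content(eto2_0, blood))
}

#' The calibration curve M(OEF) for one epoch
#'
#' Inverts the calibrated-BOLD forward equation
#' b = M (1 - f^alpha r(OEF0)^beta), with r the venous deoxyhemoglobin ratio
#' from [dhb_ratio()], giving the unique M consistent with the observation at
#' each candidate resting OEF. A hypercapnia epoch and a hyperoxia epoch each
#' trace such a curve in (OEF, M) space; their intersection is the solution.
#'
#' @param oef0 candidate resting OEF values in (0, 1); vectorized.
#' @param obs an [epoch_obs()].
#' @param bold a [bold_model()].
#' @param blood a [blood_model()].
#' @return M values (`NA` where the denominator degenerates or the venous
#'   mass balance has no physical solution; an error for scalar input).
#' @export
m_curve <- function(oef0, obs, bold = bold_model(), blood = blood_model()) {
  check_number(oef0, "oef0", lower = 1e-12, upper = 1 - 1e-12,
               allow_vec = TRUE)
  cap <- blood$phi * blood$hb / 100
  r <- dhb_ratio_core(oef0, obs$f, obs$cao2, obs$cao2_0, cap)$r
  den <- 1 - obs$f^bold$alpha * r^bold$beta
  m <- obs$b / den
  m[is.finite(den) & abs(den) < 1e-12] <- NA_real_
  if (length(oef0) == 1L && is.na(m)) {
    if (!is.na(den) && abs(den) < 1e-12)
      stop_quo2("degenerate denominator: epoch carries no dHb contrast here")
    stop_quo2("nonphysical venous content at oef0 = %g", oef0)
  }
  m
}

## Vectorized two-curve intersection solver.
## All voxel-wise arguments are plain vectors (recycled to a common length);
## cao2_0 is scalar. Returns list(m, oef, status) with integer status codes:
## 0 solved, 1 no_root, 2 multiple_roots/degenerate (lowest-OEF root
## returned), 3 invalid_m, 4 nonphysical.
GCM_STATUS <- c(solved = 0L, no_root = 1L, multiple_roots = 2L,
                invalid_m = 3L, nonphysical = 4L)

gcm_core <- function(b_hc, f_hc, cao2_hc, b_ho, f_ho, cao2_ho, cao2_0,
                     alpha, beta, cap, grid_n = 512, tol = 1e-6,
                     oef_lo = 0.005, oef_hi = 0.995, chunk = 2048L) {
  n <- max(length(b_hc), length(f_hc), length(b_ho), length(f_ho),
           length(cao2_hc), length(cao2_ho))
  b_hc <- rep_len(b_hc, n); f_hc <- rep_len(f_hc, n)
  b_ho <- rep_len(b_ho, n); f_ho <- rep_len(f_ho, n)
  cao2_hc <- rep_len(cao2_hc, n); cao2_ho <- rep_len(cao2_ho, n)
  grid <- seq(oef_lo, oef_hi, length.out = grid_n)
  sv0 <- cao2_0 * (1 - grid) / cap            # grid-only
  valid0 <- sv0 < 1
  one_m_sv0 <- 1 - sv0

  ## elementwise g evaluation for vectors of (oef, voxel index)
  g_at <- function(oef, i) {
    m_at(oef, b_hc[i], f_hc[i], cao2_hc[i]) -
      m_at(oef, b_ho[i], f_ho[i], cao2_ho[i])
  }
  m_at <- function(oef, b, f, cao2) {
    cv <- cao2 - oef * cao2_0 / f
    sv <- cv / cap
    r <- (1 - sv) / (1 - cao2_0 * (1 - oef) / cap)
    den <- 1 - f^alpha * r^beta
    m <- b / den
    m[cv < 0 | sv >= 1 | abs(den) < 1e-12] <- NA_real_
    m
  }

  m_out <- oef_out <- rep(NA_real_, n)
  status <- rep(GCM_STATUS[["nonphysical"]], n)

  for (lo_i in seq(1L, n, by = chunk)) {
    hi_i <- min(lo_i + chunk - 1L, n)
    i <- lo_i:hi_i
    nc <- length(i)
    rep_row <- function(v) matrix(v, grid_n, nc, byrow = TRUE)
    m_mat <- function(b, f, cao2) {
      cv <- rep_row(cao2) - grid %o% (cao2_0 / f)
      sv <- cv / cap
      r <- (1 - sv) / one_m_sv0            # recycles grid vector down columns
      den <- 1 - rep_row(f^alpha) * r^beta
      m <- rep_row(b) / den
      bad <- cv < 0 | sv >= 1 | !valid0 | abs(den) < 1e-12
      m[bad] <- NA_real_
      den[bad] <- NA_real_
      list(m = m, den = den)
    }
    mm_hc <- m_mat(b_hc[i], f_hc[i], cao2_hc[i])
    mm_ho <- m_mat(b_ho[i], f_ho[i], cao2_ho[i])
    gd <- mm_hc$m - mm_ho$m

    fin <- is.finite(gd)
    sgn <- sign(gd)
    prod_ok <- fin[-grid_n, , drop = FALSE] & fin[-1L, , drop = FALSE]
    ## a sign change of g across a pole of either curve (its denominator
    ## flipping sign) is a singularity, not a root
    no_pole <- (mm_hc$den[-grid_n, , drop = FALSE] *
                  mm_hc$den[-1L, , drop = FALSE] > 0) &
      (mm_ho$den[-grid_n, , drop = FALSE] *
         mm_ho$den[-1L, , drop = FALSE] > 0)
    no_pole[is.na(no_pole)] <- FALSE
    crossing <- prod_ok & no_pole &
      (sgn[-grid_n, , drop = FALSE] * sgn[-1L, , drop = FALSE] < 0)
    zero_hit <- fin & gd == 0

    for (k in seq_len(nc)) {
      vi <- i[k]
      nvalid <- sum(fin[, k])
      if (nvalid == 0L) next                          # nonphysical
      nz <- sum(zero_hit[, k])
      ncr <- sum(crossing[, k])
      if (nz >= 2L || (nz == nvalid && nvalid >= 2L)) {
        ## curves coincide (at least on the grid): degenerate intersection
        j <- which(zero_hit[, k])[1L]
        oef_out[vi] <- grid[j]
        m_out[vi] <- m_at(grid[j], b_hc[vi], f_hc[vi], cao2_hc[vi])
        status[vi] <- GCM_STATUS[["multiple_roots"]]
        next
      }
      roots <- ncr + nz
      if (roots == 0L) { status[vi] <- GCM_STATUS[["no_root"]]; next }
      if (nz == 1L && ncr == 0L) {
        j <- which(zero_hit[, k])[1L]
        root <- grid[j]
      } else {
        j <- which(crossing[, k])[1L]                 # lowest-OEF bracket
        a <- grid[j]; bnd <- grid[j + 1L]
        ga <- gd[j, k]
        while (bnd - a > tol) {
          mid <- (a + bnd) / 2
          gm_ <- g_at(mid, vi)
          if (!is.finite(gm_)) break
          if (sign(gm_) == sign(ga)) { a <- mid; ga <- gm_ } else bnd <- mid
        }
        root <- (a + bnd) / 2
      }
      mv <- m_at(root, b_hc[vi], f_hc[vi], cao2_hc[vi])
      if (!is.finite(mv)) { status[vi] <- GCM_STATUS[["nonphysical"]]; next }
      oef_out[vi] <- root
      m_out[vi] <- mv
      status[vi] <- if (mv <= 0) GCM_STATUS[["invalid_m"]]
      else if (roots > 1L) GCM_STATUS[["multiple_roots"]]
      else GCM_STATUS[["solved"]]
    }
  }
  list(m = m_out, oef = oef_out, status = status)
}

status_label <- function(code) {
  names(GCM_STATUS)[match(code, GCM_STATUS)]
}

#' Fit the generalized calibration model to one voxel or ROI
#'
#' Builds the hypercapnia and hyperoxia calibration curves M(OEF) (see
#' [m_curve()]) and locates their intersection by a sign-change scan on a
#' uniform OEF grid over (`oef_lo`, `oef_hi`) followed by bisection to
#' `|dOEF| < tol`. When several sign changes occur (noise-induced
#' multiplicity) the lowest-OEF root is returned and flagged.
#'
#' @param hc,ho [epoch_obs()] for the hypercapnic and hyperoxic epochs.
#' @param bold a [bold_model()].
#' @param blood a [blood_model()].
#' @param grid_n number of grid points for the sign-change scan.
#' @param tol bisection tolerance on OEF.
#' @param oef_lo,oef_hi open search bounds for OEF; the defaults avoid the
#'   singular endpoints where venous blood saturates.
#' @return An object of class `gcm` with elements `m`, `oef`, `status`
#'   (one of `solved`, `no_root`, `multiple_roots`, `invalid_m`,
#'   `nonphysical`) and the inputs. `coef()` returns `c(M =, OEF =)`;
#'   `plot()` draws both curves and the intersection; `fitted()` returns the
#'   BOLD changes reproduced by the solution.
#' @examples
#' bl <- blood_model()
#' hc <- obs_from_gas(0.015361, 1.25, 112, 112, bl)
#' ho <- obs_from_gas(0.0121548, 0.98, 369, 112, bl)
#' fit <- gcm_fit(hc, ho)
#' coef(fit)    # M ~ 0.060, OEF ~ 0.35
#' @export
gcm_fit <- function(hc, ho, bold = bold_model(), blood = blood_model(),
                    grid_n = 512, tol = 1e-6, oef_lo = 0.005,
                    oef_hi = 0.995) {
  stopifnot(inherits(hc, "epoch_obs"), inherits(ho, "epoch_obs"))
  if (abs(hc$cao2_0 - ho$cao2_0) > 1e-9)
    stop_quo2("gcm_fit: epochs disagree on the baseline arterial O2 content")
  cap <- blood$phi * blood$hb / 100
  sol <- gcm_core(hc$b, hc$f, hc$cao2, ho$b, ho$f, ho$cao2, hc$cao2_0,
                  bold$alpha, bold$beta, cap, grid_n = grid_n, tol = tol,
                  oef_lo = oef_lo, oef_hi = oef_hi)
  structure(list(m = sol$m, oef = sol$oef,
                 status = status_label(sol$status),
                 hc = hc, ho = ho, bold = bold, blood = blood,
                 grid_n = grid_n, tol = tol,
                 oef_bounds = c(oef_lo, oef_hi)),
            class = "gcm")
}

#' @rdname gcm_fit
#' @export
solve_intersection <- gcm_fit

#' @export
print.gcm <- function(x, ...) {
  cat("Generalized calibration model fit\n")
  if (identical(x$status, "solved") || identical(x$status, "multiple_roots")) {
    cat(sprintf("  M = %.4f, OEF = %.4f  [%s]\n", x$m, x$oef, x$status))
  } else {
    cat(sprintf("  no solution [%s]\n", x$status))
  }
  invisible(x)
}

#' @export
coef.gcm <- function(object, ...) c(M = object$m, OEF = object$oef)

#' @export
summary.gcm <- function(object, ...) {
  out <- list(coef = coef(object), status = object$status,
              b = c(hc = object$hc$b, ho = object$ho$b),
              f = c(hc = object$hc$f, ho = object$ho$f),
              alpha = object$bold$alpha, beta = object$bold$beta)
  class(out) <- "summary.gcm"
  out
}

#' @export
print.summary.gcm <- function(x, ...) {
  cat("GCM fit summary\n")
  cat(sprintf("  status: %s\n", x$status))
  cat(sprintf("  M = %.4f  OEF = %.4f\n", x$coef[1L], x$coef[2L]))
  cat(sprintf("  inputs: b_hc %.5f (f %.3f), b_ho %.5f (f %.3f)\n",
              x$b[1L], x$f[1L], x$b[2L], x$f[2L]))
  cat(sprintf("  exponents: alpha %.2f, beta %.2f\n", x$alpha, x$beta))
  invisible(x)
}

#' @export
fitted.gcm <- function(object, ...) {
  if (!object$status %in% c("solved", "multiple_roots"))
    return(c(b_hc = NA_real_, b_ho = NA_real_))
  fwd <- function(obs) {
    r <- dhb_ratio(object$oef, obs$f, obs$cao2, obs$cao2_0, object$blood)
    object$m * (1 - obs$f^object$bold$alpha * r^object$bold$beta)
  }
  c(b_hc = fwd(object$hc), b_ho = fwd(object$ho))
}

#' @export
residuals.gcm <- function(object, ...) {
  c(b_hc = object$hc$b, b_ho = object$ho$b) - fitted(object)
}

#' @export
plot.gcm <- function(x, n = 200, ...) {
  oef <- seq(x$oef_bounds[1L], x$oef_bounds[2L], length.out = n)
  mh <- m_curve(oef, x$hc, x$bold, x$blood)
  mo <- m_curve(oef, x$ho, x$bold, x$blood)
  ylim <- range(c(mh, mo, x$m), finite = TRUE)
  graphics::plot(oef, mh, type = "l", col = "firebrick", lwd = 2,
                 xlab = "resting OEF", ylab = "M", ylim = ylim, ...)
  graphics::lines(oef, mo, col = "steelblue", lwd = 2)
  if (x$status %in% c("solved", "multiple_roots"))
    graphics::points(x$oef, x$m, pch = 19)
  graphics::legend("topleft", c("HC curve", "HO curve"), lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Absolute resting CMRO2 from a solved OEF
#'
#' CMRO2 = OEF x CBF0 x CaO2_0 x k, in micromol O2 per 100 g per minute;
#' k converts ml O2 to micromol (44.6 micromol/ml at STP).
#'
#' @param oef resting oxygen extraction fraction (vectorized).
#' @param cbf0 baseline CBF, ml/100g/min.
#' @param cao2_0 baseline arterial O2 content, ml O2/ml blood.
#' @param k_umol_per_ml micromol of O2 per ml of O2 gas.
#' @return CMRO2 in micromol/100g/min.
#' @export
cmro2_from_solution <- function(oef, cbf0, cao2_0, k_umol_per_ml = 44.6) {
  if (any(oef < 0 | cbf0 < 0 | cao2_0 < 0, na.rm = TRUE))
    stop_quo2("cmro2_from_solution: inputs must be non-negative")
  oef * cbf0 * cao2_0 * k_umol_per_ml
}
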