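#' Blood oxygen-carriage model
#'
#' Bundles the constants describing how arterial blood carries oxygen and how
#' its longitudinal relaxation rate responds to dissolved O2. End-tidal O2 is
#' used as a surrogate for arterial PaO2 throughout the package.
#'
#' The default relaxivity slope `r1_slope` is calibrated so that the linear
#' R1(PaO2) model passes through T1 = `t1_ref` at `pao2_ref` and through
#' 1.56 s at 369 mmHg, the arterial-blood values adopted for normoxia and for
#' a 60%-O2 hyperoxic state at 3 T. On that line a 100%-O2 state
#' (PaO2 about 654 mmHg) has T1 of about 1.47 s.
#'
#' @param hb hemoglobin concentration, g/dl.
#' @param phi O2-carrying capacity of hemoglobin, ml O2 per g Hb.
#' @param eps plasma O2 solubility, ml O2/(dl mmHg).
#' @param t1_ref normoxic arterial blood T1, seconds.
#' @param pao2_ref PaO2 anchor for `t1_ref`, mmHg.
#' @param r1_slope d(1/T1)/dPaO2 in 1/s/mmHg; `NULL` uses the two-point
#'   calibration described above.
#' @return An object of class `blood_model`.
#' @examples
#' bl <- blood_model()
#' blood_t1(654, bl)  # ~1.47 s
#' @export
blood_model <- function(hb = 15, phi = 1.34, eps = 0.0031,
                        t1_ref = 1.65, pao2_ref = 112, r1_slope = NULL) {
  check_number(hb, "hb", lower = 1e-8)
  check_number(phi, "phi", lower = 1e-8)
  check_number(eps, "eps", lower = 1e-12)
  check_number(t1_ref, "t1_ref", lower = 1e-8)
  check_number(pao2_ref, "pao2_ref", lower = 1e-8)
  if (is.null(r1_slope))
    r1_slope <- (1 / 1.56 - 1 / 1.65) / (369 - 112)
  check_number(r1_slope, "r1_slope", lower = 0)
  structure(list(hb = hb, phi = phi, eps = eps, t1_ref = t1_ref,
                 pao2_ref = pao2_ref, r1_slope = r1_slope),
            class = "blood_model")
}

#' @export
print.blood_model <- function(x, ...) {
  cat("Blood oxygen-carriage model\n")
  cat(sprintf("  [Hb] %.3g g/dl, phi %.3g ml O2/g, eps %.4g ml O2/(dl mmHg)\n",
              x$hb, x$phi, x$eps))
  cat(sprintf("  T1 %.3g s at PaO2 %.4g mmHg, dR1/dPaO2 %.4g /s/mmHg\n",
              x$t1_ref, x$pao2_ref, x$r1_slope))
  invisible(x)
}

#' Severinghaus hemoglobin saturation
#'
#' SaO2 = 1 / (23400 / (PaO2^3 + 150 PaO2) + 1). Strictly increasing in PaO2
#' and approaching 1 as PaO2 grows.
#'
#' @param pao2 arterial O2 partial pressure, mmHg (> 0); vectorized.
#' @return Saturation as a fraction in (0, 1).
#' @export
sao2_severinghaus <- function(pao2) {
  check_number(pao2, "pao2", lower = .Machine$double.eps, allow_vec = TRUE)
  1 / (23400 / (pao2^3 + 150 * pao2) + 1)
}

#' Arterial oxygen content
#'
#' CaO2 = (phi * hb * SaO2 + eps * PaO2) / 100, in ml O2 per ml blood
#' (hemoglobin-bound plus dissolved; /100 converts ml/dl to ml/ml).
#'
#' @inheritParams sao2_severinghaus
#' @param blood a [blood_model()].
#' @return CaO2 in ml O2/ml blood.
#' @export
arterial_o2_content <- function(pao2, blood = blood_model()) {
  check_number(pao2, "pao2", lower = .Machine$double.eps, allow_vec = TRUE)
  (blood$phi * blood$hb * sao2_severinghaus(pao2) + blood$eps * pao2) / 100
}

## vectorized mass-balance core used by dhb_ratio() and the GCM solver.
## cap = phi*hb/100 (ml O2/ml blood). Venous dissolved O2 is neglected.
## Returns list(r, ok, saturated): ok FALSE where CvO2 < 0 or SvO2/SvO2_0
## reach 1 (no real dHb).
dhb_ratio_core <- function(oef0, f, cao2_epoch, cao2_0, cap) {
  cv <- cao2_epoch - oef0 * cao2_0 / f
  sv <- cv / cap
  sv0 <- cao2_0 * (1 - oef0) / cap
  bad <- cv < 0
  sat <- sv >= 1 | sv0 >= 1
  r <- (1 - sv) / (1 - sv0)
  r[bad | sat] <- NA_real_
  list(r = r, ok = !(bad | sat), saturated = sat & !bad)
}

#' Venous deoxyhemoglobin concentration ratio
#'
#' Ratio r = dHb/dHb0 of venous deoxyhemoglobin during a respiratory epoch to
#' its baseline value, from an O2 mass balance at fixed O2 consumption
#' (hyperoxia treated as isometabolic): venous content
#' CvO2 = CaO2_epoch - OEF0 * CaO2_0 / f, venous saturation SvO2 = CvO2 / cap
#' with capacity cap = phi * hb / 100, and r = (1 - SvO2) / (1 - SvO2_0).
#' At f = 1 and unchanged arterial content r = 1.
#'
#' @param oef0 resting oxygen extraction fraction, in (0, 1).
#' @param f CBF during the epoch relative to baseline (> 0).
#' @param cao2_epoch,cao2_0 arterial O2 content during the epoch and at
#'   baseline, ml O2/ml blood.
#' @param blood a [blood_model()].
#' @return The dimensionless ratio. If venous blood would be fully saturated
#'   the value is `NA` with attribute `saturated = TRUE`.
#' @export
dhb_ratio <- function(oef0, f, cao2_epoch, cao2_0, blood = blood_model()) {
  check_number(oef0, "oef0", lower = 1e-12, upper = 1 - 1e-12, allow_vec = TRUE)
  check_number(f, "f", lower = 1e-12, allow_vec = TRUE)
  check_number(cao2_epoch, "cao2_epoch", lower = 1e-12, allow_vec = TRUE)
  check_number(cao2_0, "cao2_0", lower = 1e-12, allow_vec = TRUE)
  cap <- blood$phi * blood$hb / 100
  out <- dhb_ratio_core(oef0, f, cao2_epoch, cao2_0, cap)
  if (any(!out$ok & !out$saturated))
    stop_quo2("nonphysical venous content: extraction exceeds O2 delivery")
  if (any(out$saturated)) {
    warning("fully saturated venous blood: no real dHb at these inputs",
            call. = FALSE)
    attr(out$r, "saturated") <- TRUE
  }
  out$r
}

#' Arterial blood T1 as a function of PaO2
#'
#' Linear relaxation-rate model R1 = 1/t1_ref + r1_slope * (PaO2 - pao2_ref);
#' returns T1 = 1/R1, which decreases as dissolved O2 rises.
#'
#' @inheritParams arterial_o2_content
#' @return T1 in seconds.
#' @export
blood_t1 <- function(pao2, blood = blood_model()) {
  check_number(pao2, "pao2", lower = .Machine$double.eps, allow_vec = TRUE)
  r1 <- 1 / blood$t1_ref + blood$r1_slope * (pao2 - blood$pao2_ref)
  if (any(r1 <= 0))
    stop_quo2("blood_t1: model yields non-positive R1 at PaO2 = %g",
              pao2[which(r1 <= 0)[1L]])
  1 / r1
}
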