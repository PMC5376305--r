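#' Sensitivity of the calibration solution to hyperoxia-level inputs
#'
#' Varies one hyperoxia-epoch input — the end-tidal O2 (`eto2_ho`), the
#' fractional BOLD change (`b_ho`) or the CBF ratio (`f_ho`) — across a range
#' bracketing two inspired-O2 protocols while all other inputs stay at their
#' fixed values, and re-solves the model at each step. This traces how the
#' hyperoxia calibration curve slides along the (nearly horizontal) section of
#' the hypercapnia curve.
#'
#' @param parameter which hyperoxia input to sweep.
#' @param low,high sweep endpoints, in the parameter's units (mmHg for
#'   `eto2_ho`, dimensionless otherwise).
#' @param n_steps number of evenly spaced steps (>= 2; a zero-width range
#'   `low == high` repeats the base solution).
#' @param hc,ho fixed [epoch_obs()] pair (the hyperoxia epoch supplies values
#'   for the parameters not being swept).
#' @param eto2_0 baseline end-tidal O2 (mmHg) used to rebuild arterial content
#'   when `eto2_ho` is swept.
#' @param bold,blood model settings.
#' @param cbf0 baseline CBF (ml/100g/min) used to report CMRO2.
#' @param k_umol_per_ml ml-to-micromol O2 conversion.
#' @return A data frame with columns `parameter`, `value`, `m`, `oef`,
#'   `cmro2`, `status`.
#' @export
gcm_sweep <- function(parameter = c("eto2_ho", "b_ho", "f_ho"),
                      low, high, n_steps = 6, hc, ho, eto2_0 = 112,
                      bold = bold_model(), blood = blood_model(),
                      cbf0 = 60, k_umol_per_ml = 44.6) {
  parameter <- match.arg(parameter)
  check_number(low, "low"); check_number(high, "high")
  if (low > high) stop_quo2("gcm_sweep: low must be <= high")
  if (n_steps < 2) stop_quo2("gcm_sweep: n_steps must be >= 2")
  vals <- if (low == high) rep(low, n_steps)
  else seq(low, high, length.out = n_steps)
  rows <- lapply(vals, function(v) {
    ho_v <- ho
    if (parameter == "eto2_ho") ho_v$cao2 <- arterial_o2_content(v, blood)
    if (parameter == "b_ho") ho_v$b <- v
    if (parameter == "f_ho") ho_v$f <- v
    fit <- gcm_fit(hc, ho_v, bold, blood)
    data.frame(parameter = parameter, value = v, m = fit$m, oef = fit$oef,
               cmro2 = if (fit$status == "solved")
                 cmro2_from_solution(fit$oef, cbf0, hc$cao2_0, k_umol_per_ml)
               else NA_real_,
               status = fit$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Combined self-consistent hyperoxia-level sweep
#'
#' Moves the hyperoxia end-tidal O2 and CBF ratio jointly between two protocol
#' endpoints while regenerating the hyperoxia BOLD change from a fixed ground
#' truth (M, OEF) through the forward model — i.e. emulates what the scanner
#' would actually measure at each inspired-O2 level. Because all three inputs
#' move consistently, the solved (M, OEF) should be invariant across the
#' sweep; this is the model's O2-level self-consistency property.
#'
#' @param m_true,oef_true ground-truth calibration parameters.
#' @param hc fixed hypercapnia [epoch_obs()].
#' @param eto2_range length-2 range of hyperoxic end-tidal O2, mmHg.
#' @param f_ho_range length-2 range of true hyperoxia CBF ratios.
#' @param n_steps number of steps.
#' @inheritParams gcm_sweep
#' @return A data frame as in [gcm_sweep()], with `parameter = "combined"`
#'   and `value` the swept ETO2.
#' @export
gcm_sweep_combined <- function(m_true, oef_true, hc,
                               eto2_range = c(369, 654),
                               f_ho_range = c(0.98, 0.98), n_steps = 6,
                               eto2_0 = 112, bold = bold_model(),
                               blood = blood_model(), cbf0 = 60,
                               k_umol_per_ml = 44.6) {
  check_number(m_true, "m_true", lower = 1e-9)
  check_number(oef_true, "oef_true", lower = 1e-9, upper = 1 - 1e-9)
  eto2 <- seq(eto2_range[1L], eto2_range[2L], length.out = n_steps)
  f_ho <- seq(f_ho_range[1L], f_ho_range[2L], length.out = n_steps)
  cao2_0 <- arterial_o2_content(eto2_0, blood)
  rows <- lapply(seq_len(n_steps), function(s) {
    cao2_ho <- arterial_o2_content(eto2[s], blood)
    r <- dhb_ratio(oef_true, f_ho[s], cao2_ho, cao2_0, blood)
    b_ho <- m_true * (1 - f_ho[s]^bold$alpha * r^bold$beta)
    fit <- gcm_fit(hc, epoch_obs(b_ho, f_ho[s], cao2_ho, cao2_0),
                   bold, blood)
    data.frame(parameter = "combined", value = eto2[s], m = fit$m,
               oef = fit$oef,
               cmro2 = if (fit$status == "solved")
                 cmro2_from_solution(fit$oef, cbf0, cao2_0, k_umol_per_ml)
               else NA_real_,
               status = fit$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
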