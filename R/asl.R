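#' Dual-echo pCASL acquisition parameters
#'
#' Defaults follow a 2D dual-echo pseudo-continuous ASL protocol at 3 T:
#' TR 4.12 s, TE1/TE2 8.4/30 ms, 2-s labeling, nominal first-slice
#' post-labeling delay 0.9 s and 21 ascending slices whose last slice is read
#' 1.986 s after labeling (slice increment (1.986 - 0.9)/20 s, brain-averaged
#' PLD 1.443 s). Labeling efficiency 0.85 and blood-tissue partition
#' coefficient 0.9 ml/g are standard pCASL values.
#'
#' @param tr repetition time, s.
#' @param te1,te2 echo times, s (te1 < te2).
#' @param tau label duration, s.
#' @param pld0 nominal first-slice post-labeling delay, s.
#' @param n_slices number of slices.
#' @param slice_dt per-slice acquisition increment, s.
#' @param inv_eff labeling (inversion) efficiency, fraction in (0, 1].
#' @param lam blood-tissue water partition coefficient, ml/g.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(tr = 4.12, te1 = 0.0084, te2 = 0.030, tau = 2,
                       pld0 = 0.9, n_slices = 21,
                       slice_dt = (1.986 - 0.9) / 20,
                       inv_eff = 0.85, lam = 0.9) {
  check_number(tr, "tr", lower = 1e-6)
  check_number(te1, "te1", lower = 1e-9)
  check_number(te2, "te2", lower = 1e-9)
  if (te1 >= te2) stop_quo2("acq_params: te1 must be < te2")
  check_number(tau, "tau", lower = 1e-9)
  check_number(pld0, "pld0", lower = 1e-9)
  check_number(slice_dt, "slice_dt", lower = 1e-12)
  check_number(n_slices, "n_slices", lower = 1)
  if (inv_eff <= 0 || inv_eff > 1)
    stop_quo2("acq_params: inv_eff must be in (0, 1]")
  check_number(lam, "lam", lower = 1e-9)
  structure(list(tr = tr, te1 = te1, te2 = te2, tau = tau, pld0 = pld0,
                 n_slices = as.integer(n_slices), slice_dt = slice_dt,
                 inv_eff = inv_eff, lam = lam),
            class = "acq_params")
}

#' Post-labeling delay of a slice
#'
#' Slices are acquired ascending; slice `i` (0-based) is read at
#' `pld0 + i * slice_dt` after the end of labeling.
#'
#' @param slice_index 0-based slice index (vectorized).
#' @param acq an [acq_params()].
#' @return PLD in seconds.
#' @export
slice_pld <- function(slice_index, acq = acq_params()) {
  if (any(slice_index < 0) || any(slice_index >= acq$n_slices))
    stop_quo2("slice_pld: slice_index out of range [0, %d)", acq$n_slices)
  acq$pld0 + slice_index * acq$slice_dt
}

## single-compartment pCASL kernel D(T1) = T1 (1 - exp(-tau/T1)) exp(-PLD/T1)
asl_kernel <- function(t1, tau, pld) {
  t1 * (1 - exp(-tau / t1)) * exp(-pld / t1)
}

resolve_pld <- function(slice_index, acq, pld) {
  if (!is.null(pld)) return(pld)
  if (is.null(slice_index))
    stop_quo2("either slice_index or pld must be given")
  slice_pld(slice_index, acq)
}

#' Quantify CBF from a pCASL difference signal
#'
#' Single-compartment model:
#' CBF = 6000 lambda dM / (2 alpha_inv M0 T1b (1 - exp(-tau/T1b)) exp(-PLD/T1b))
#' in ml/100g/min, linear in `dm / m0`.
#'
#' @param dm control-label difference signal (arbitrary scanner units).
#' @param m0 equilibrium (control) signal; voxels with `m0 <= 0` return `NA`.
#' @param t1b arterial blood T1, s.
#' @param slice_index 0-based slice index used to derive the PLD; ignored when
#'   `pld` is given.
#' @param acq an [acq_params()].
#' @param pld optional explicit post-labeling delay, s.
#' @return CBF in ml/100g/min.
#' @export
cbf_quantify <- function(dm, m0, t1b, slice_index = NULL, acq = acq_params(),
                         pld = NULL) {
  check_number(t1b, "t1b", lower = 1e-9, allow_vec = TRUE)
  pld <- resolve_pld(slice_index, acq, pld)
  out <- 6000 * acq$lam * dm /
    (2 * acq$inv_eff * m0 * asl_kernel(t1b, acq$tau, pld))
  out[!is.finite(m0) | m0 <= 0] <- NA_real_
  out
}

#' Slice-wise hyperoxia T1 corrective factor
#'
#' Ratio D(t1_ref)/D(t1_ho) of the pCASL quantification kernel evaluated at
#' the normoxic and hyperoxic arterial blood T1. Multiplying a hyperoxia CBF
#' value quantified with the normoxic T1 by this factor removes the apparent
#' flow decrease created by T1 shortening alone. The factor is 1 when
#' `t1_ho == t1_ref` and exceeds 1 when the blood T1 shortens.
#'
#' @param t1_ref normoxic arterial blood T1, s.
#' @param t1_ho hyperoxic arterial blood T1, s.
#' @inheritParams cbf_quantify
#' @return Dimensionless corrective factor.
#' @export
t1_correction_factor <- function(t1_ref, t1_ho, slice_index = NULL,
                                 acq = acq_params(), pld = NULL) {
  check_number(t1_ref, "t1_ref", lower = 1e-9)
  check_number(t1_ho, "t1_ho", lower = 1e-9, allow_vec = TRUE)
  pld <- resolve_pld(slice_index, acq, pld)
  asl_kernel(t1_ref, acq$tau, pld) / asl_kernel(t1_ho, acq$tau, pld)
}

#' Change in apparent transverse relaxation rate
#'
#' dR2* = -log(s_epoch / s_base) / te2, in 1/s. Negative for a BOLD signal
#' increase; positive values under hyperoxia flag susceptibility artifact.
#'
#' @param s_epoch,s_base mean signals during the epoch and at baseline;
#'   non-positive signals return `NA`.
#' @param te2 echo time of the BOLD echo, s.
#' @return dR2* in 1/s.
#' @export
delta_r2star <- function(s_epoch, s_base, te2) {
  check_number(te2, "te2", lower = 1e-9)
  bad <- !is.finite(s_epoch) | !is.finite(s_base) | s_epoch <= 0 | s_base <= 0
  ratio <- s_epoch / s_base
  ratio[bad] <- 1
  out <- -log(ratio) / te2
  out[bad] <- NA_real_
  out
}

#' Fraction of gray-matter voxels with positive dR2*
#'
#' Percentage of GM voxels whose hyperoxia dR2* is positive — a quality-control
#' index of paramagnetic-O2 susceptibility artifact around the air cavities.
#'
#' @param dr2s dR2* map (array).
#' @param gm_mask logical array (or 0/1) of GM voxels.
#' @return Percent in [0, 100].
#' @export
positive_dr2s_fraction <- function(dr2s, gm_mask) {
  m <- as.logical(gm_mask)
  if (length(m) != length(dr2s))
    stop_quo2("positive_dr2s_fraction: map and mask sizes differ")
  n <- sum(m, na.rm = TRUE)
  if (n == 0L) stop_quo2("positive_dr2s_fraction: empty GM mask")
  100 * sum(dr2s[m] > 0, na.rm = TRUE) / n
}

#' Per-voxel response set
#'
#' Container for the per-epoch quantities consumed by the calibration solver.
#'
#' @param b_hc,b_ho 3D arrays of fractional BOLD change during hypercapnia and
#'   hyperoxia.
#' @param f_hc 3D array of CBF ratio during hypercapnia.
#' @param f_ho_global single GM-derived CBF ratio during hyperoxia.
#' @param cbf0 3D array of baseline CBF, ml/100g/min.
#' @param dr2s_ho 3D array of dR2* during hyperoxia (diagnostic).
#' @param mask logical 3D parenchyma mask.
#' @param gm 3D array of GM probability in [0, 1].
#' @param extras optional list carried along (e.g. simulation ground truth).
#' @return An object of class `response_set`.
#' @export
response_set <- function(b_hc, b_ho, f_hc, f_ho_global, cbf0, dr2s_ho,
                         mask, gm, extras = list()) {
  dm <- dim(b_hc)
  for (a in list(b_ho, f_hc, cbf0, dr2s_ho, mask, gm))
    if (!identical(dim(a), dm))
      stop_quo2("response_set: all maps must share the same geometry")
  check_number(f_ho_global, "f_ho_global", lower = 1e-9)
  msk <- as.logical(mask); dim(msk) <- dm
  if (any(f_hc[msk] <= 0, na.rm = TRUE))
    stop_quo2("response_set: f_hc must be positive inside the mask")
  if (any(cbf0[msk] < 0, na.rm = TRUE))
    stop_quo2("response_set: cbf0 must be non-negative inside the mask")
  structure(list(b_hc = b_hc, b_ho = b_ho, f_hc = f_hc,
                 f_ho_global = f_ho_global, cbf0 = cbf0, dr2s_ho = dr2s_ho,
                 mask = msk, gm = gm, dim = dm, extras = extras),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("Response set: %s grid, %d parenchymal voxels, f_ho(GM) = %.3f\n",
              paste(x$dim, collapse = "x"), sum(x$mask), x$f_ho_global))
  invisible(x)
}

## classify volume times into steady-state window classes; samples whose
## neighborhood [t - guard, t + guard] crosses a block boundary are dropped so
## that interpolated control values never straddle an epoch transition.
classify_times <- function(times, par, policy, guard = 0) {
  w <- epoch_windows(par, policy)
  cls <- rep(NA_character_, length(times))
  assign_win <- function(win, lab) {
    if (is.null(win)) return()
    for (i in seq_len(nrow(win)))
      cls[times >= win[i, 1L] & times <= win[i, 2L]] <<- lab
  }
  assign_win(w$baseline, "baseline")
  assign_win(w$hc, "hc")
  assign_win(w$ho, "ho")
  if (guard > 0) {
    blk_of <- function(tt) findInterval(tt, par$start)
    bad <- blk_of(pmax(times - guard, 0)) != blk_of(pmin(times + guard,
                                                         max(par$end) - 1e-9))
    cls[bad] <- NA_character_
  }
  cls
}

#' Extract epoch responses from dual-echo pCASL series
#'
#' Converts 4D dual-echo series into the [response_set()] the calibration
#' solver needs. Echo-1 volumes alternate control/label; the perfusion series
#' is built by surround subtraction (the control series linearly interpolated
#' to label times). Baseline CBF is quantified with the normoxic blood T1;
#' hyperoxia-epoch CBF ratios receive the slice-wise [t1_correction_factor()]
#' at the hyperoxic blood T1 derived from the measured end-tidal O2. BOLD
#' fractional changes and dR2* come from the echo-2 control series, averaged
#' over the same steady-state windows used for the gases. The uniform
#' hyperoxia CBF change `f_ho_global` is the GM-probability-weighted mean over
#' voxels with GM probability >= 0.5.
#'
#' @param echo1,echo2 4D arrays (x, y, z, volume).
#' @param par a [paradigm()] aligned with the acquisition.
#' @param acq an [acq_params()].
#' @param gas an [epoch_gas_summary()] (supplies the hyperoxic ETO2).
#' @param blood a [blood_model()].
#' @param gm 3D GM-probability array.
#' @param mask optional 3D parenchyma mask; defaults to voxels whose baseline
#'   control signal exceeds the `m0_percentile` percentile of positive values.
#' @param control_first `TRUE` when volume 1 is a control image.
#' @param t1_correct apply the hyperoxia T1 correction (default `TRUE`).
#' @param policy a [window_policy()].
#' @param m0_percentile percentile (0-100) of the baseline signal used for the
#'   default mask.
#' @return A [response_set()].
#' @export
extract_responses <- function(echo1, echo2, par, acq = acq_params(),
                              gas, blood = blood_model(), gm,
                              mask = NULL, control_first = TRUE,
                              t1_correct = TRUE, policy = window_policy(),
                              m0_percentile = 20) {
  d <- dim(echo1)
  if (length(d) != 4L || !identical(dim(echo2), d))
    stop_quo2("extract_responses: echo1/echo2 must be matching 4D arrays")
  if (d[3L] != acq$n_slices)
    stop_quo2("extract_responses: %d slices in data vs %d in acq_params",
              d[3L], acq$n_slices)
  nvol <- d[4L]
  expected <- floor(max(par$end) / acq$tr)
  if (abs(nvol - expected) > 1L)
    stop_quo2("paradigm misalignment: %d volumes but paradigm implies %d",
              nvol, expected)
  times <- (seq_len(nvol) - 1L) * acq$tr
  ctrl <- seq(if (control_first) 1L else 2L, nvol, by = 2L)
  labl <- seq(if (control_first) 2L else 1L, nvol, by = 2L)

  nvox <- prod(d[1:3])
  flat <- matrix(echo1, nrow = nvox)
  c1 <- flat[, ctrl, drop = FALSE]
  l1 <- flat[, labl, drop = FALSE]
  ## linear interpolation of the control series to label times, per voxel:
  ## label k sits between controls; weights from the time grid (shared).
  tc <- times[ctrl]; tl <- times[labl]
  idx <- findInterval(tl, tc)
  idx0 <- pmax(idx, 1L); idx1 <- pmin(idx + 1L, length(tc))
  wgt <- ifelse(idx1 == idx0, 0,
                (tl - tc[idx0]) / (tc[idx1] - tc[idx0]))
  ci <- c1[, idx0, drop = FALSE] * rep(1 - wgt, each = nvox) +
    c1[, idx1, drop = FALSE] * rep(wgt, each = nvox)
  dm <- ci - l1                               # perfusion-weighted series

  cls_lab <- classify_times(tl, par, policy, guard = 2 * acq$tr)
  cls_ctl <- classify_times(tc, par, policy, guard = 0)

  mean_cols <- function(m, sel) {
    if (!any(sel)) stop_quo2("empty epoch window: no usable volumes")
    rowMeans(m[, sel, drop = FALSE])
  }
  dm_base <- mean_cols(dm, !is.na(cls_lab) & cls_lab == "baseline")
  dm_hc   <- mean_cols(dm, !is.na(cls_lab) & cls_lab == "hc")
  dm_ho   <- mean_cols(dm, !is.na(cls_lab) & cls_lab == "ho")
  m0      <- mean_cols(c1, !is.na(cls_ctl) & cls_ctl == "baseline")

  if (is.null(mask)) {
    thr <- stats::quantile(m0[m0 > 0], m0_percentile / 100, names = FALSE)
    mask <- array(m0 >= thr, dim = d[1:3])
  }
  msk <- as.logical(mask); dim(msk) <- d[1:3]

  zidx <- rep(seq_len(d[3L]) - 1L, each = d[1L] * d[2L])
  pld <- slice_pld(zidx, acq)
  cbf0 <- 6000 * acq$lam * dm_base /
    (2 * acq$inv_eff * m0 * asl_kernel(blood$t1_ref, acq$tau, pld))
  cbf0[!is.finite(cbf0) | m0 <= 0] <- NA_real_
  cbf0[cbf0 < 0] <- 0

  f_hc <- dm_hc / dm_base
  f_ho <- dm_ho / dm_base
  if (t1_correct) {
    t1_ho <- blood_t1(gas$eto2_ho, blood)
    f_ho <- f_ho * t1_correction_factor(blood$t1_ref, t1_ho, acq = acq,
                                        pld = pld)
  }
  gmv <- as.numeric(gm)
  wsel <- msk & gmv >= 0.5 & is.finite(f_ho)
  if (!any(wsel))
    stop_quo2("extract_responses: no GM voxels (probability >= 0.5) in mask")
  f_ho_global <- sum(f_ho[wsel] * gmv[wsel]) / sum(gmv[wsel])

  flat2 <- matrix(echo2, nrow = nvox)[, ctrl, drop = FALSE]
  s_base <- mean_cols(flat2, !is.na(cls_ctl) & cls_ctl == "baseline")
  s_hc   <- mean_cols(flat2, !is.na(cls_ctl) & cls_ctl == "hc")
  s_ho   <- mean_cols(flat2, !is.na(cls_ctl) & cls_ctl == "ho")
  b_hc <- s_hc / s_base - 1
  b_ho <- s_ho / s_base - 1
  dr2s <- delta_r2star(s_ho, s_base, acq$te2)

  shape <- function(v) array(v, dim = d[1:3])
  f_hc_a <- shape(f_hc)
  f_hc_a[msk & (!is.finite(f_hc_a) | f_hc_a <= 0)] <- NA_real_
  msk <- msk & is.finite(f_hc_a) & f_hc_a > 0 & is.finite(shape(cbf0))
  response_set(shape(b_hc), shape(b_ho), f_hc_a, f_ho_global,
               shape(cbf0), shape(dr2s), msk, array(gmv, d[1:3]))
}
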