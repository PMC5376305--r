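## shared fixtures for the test suite (everything generated in code)

fix_blood <- blood_model()
fix_bold <- bold_model()
fix_acq <- acq_params()
fix_cao2_0 <- arterial_o2_content(112, fix_blood)
fix_cao2_lho <- arterial_o2_content(369, fix_blood)
fix_cao2_hho <- arterial_o2_content(654, fix_blood)

## forward BOLD fraction at a known ground truth
forward_b <- function(m, oef, f, cao2, cao2_0 = fix_cao2_0,
                      bold = fix_bold, blood = fix_blood) {
  r <- dhb_ratio(oef, f, cao2, cao2_0, blood)
  m * (1 - f^bold$alpha * r^bold$beta)
}

## canonical single-voxel observation pair (M = 0.06, OEF = 0.35)
make_obs_pair <- function(m = 0.06, oef = 0.35, f_hc = 1.25, f_ho = 0.98,
                          eto2_ho = 369) {
  cao2_ho <- arterial_o2_content(eto2_ho, fix_blood)
  list(
    hc = epoch_obs(forward_b(m, oef, f_hc, fix_cao2_0), f_hc,
                   fix_cao2_0, fix_cao2_0),
    ho = epoch_obs(forward_b(m, oef, f_ho, cao2_ho), f_ho,
                   cao2_ho, fix_cao2_0)
  )
}

## square-ish breathing waveform with expiratory plateau `plateau`
breath_wave <- function(duration, rate_bpm, plateau, insp = 2,
                        sample_rate = 25) {
  t <- seq(0, duration, by = 1 / sample_rate)
  period <- 60 / rate_bpm
  ph <- (t %% period) / period
  w <- numeric(length(ph))
  ramp <- ph >= 0.35 & ph < 0.5
  w[ramp] <- (1 - cos(pi * (ph[ramp] - 0.35) / 0.15)) / 2
  w[ph >= 0.5] <- 1
  if (length(plateau) == 1L) plateau <- rep(plateau, length(t))
  list(t = t, p = insp + (plateau - insp) * w)
}

## tiny simulated subject for timeseries tests
small_scene <- function(seed = 3) synth_scene(dim = c(12, 12, 6),
                                              wedge_frac = 0, seed = seed)
small_acq <- acq_params(n_slices = 6, slice_dt = (1.986 - 0.9) / 5)
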