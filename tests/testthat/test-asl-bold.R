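test_that("slice PLDs reproduce the 2D readout timing", {
  expect_equal(slice_pld(0, fix_acq), 0.9)
  expect_equal(slice_pld(20, fix_acq), 1.986, tolerance = 1e-9)
  expect_equal(mean(slice_pld(0:20, fix_acq)), 1.443, tolerance = 1e-9)
  expect_error(slice_pld(21, fix_acq), "out of range")
})

test_that("CBF quantification is linear and matches hand evaluation", {
  expect_equal(cbf_quantify(0, 1, 1.65, pld = 1.443), 0)
  v <- cbf_quantify(0.01, 1, 1.65, pld = 1.443)
  expect_equal(v, 6000 * 0.9 * 0.01 / (2 * 0.85 * 0.4833),
               tolerance = 1e-3)
  expect_equal(cbf_quantify(0.02, 1, 1.65, pld = 1.443), 2 * v)
  expect_true(is.na(cbf_quantify(0.01, 0, 1.65, pld = 1.443)))
})

test_that("T1 corrective factor behaves as the kernel ratio", {
  expect_equal(t1_correction_factor(1.65, 1.65, pld = 1.443), 1)
  expect_equal(t1_correction_factor(1.65, 1.47, pld = 1.443), 1.180,
               tolerance = 1e-3)
  expect_equal(t1_correction_factor(1.65, 1.56, pld = 1.443), 1.081,
               tolerance = 1e-3)
  ## >= 1 whenever T1 shortens, increasing as it shortens, and with PLD
  t1s <- seq(1.65, 1.40, by = -0.05)
  fac <- vapply(t1s, function(t1)
    t1_correction_factor(1.65, t1, pld = 1.443), 0)
  expect_true(all(fac >= 1))
  expect_true(all(diff(fac) > 0))
  plds <- slice_pld(0:20, fix_acq)
  fac_pld <- t1_correction_factor(1.65, 1.47, acq = fix_acq, pld = plds)
  expect_true(all(diff(fac_pld) > 0))
})

test_that("correction shrinks a purely T1-driven apparent CBF decrease", {
  ## true change 0: the apparent ratio is D(t1_ho)/D(t1_ref) < 1, and the
  ## corrected change must be smaller in magnitude than the uncorrected one
  for (t1_ho in c(1.47, 1.56)) {
    fac <- t1_correction_factor(1.65, t1_ho, pld = 1.443)
    apparent <- 1 / fac
    expect_lt(apparent, 1)
    uncorrected_change <- apparent - 1
    corrected_change <- apparent * fac - 1
    expect_lt(abs(corrected_change), abs(uncorrected_change))
    expect_lt(abs(corrected_change), 1e-12)
  }
})

test_that("quantification inverts the forward signal model exactly", {
  acq <- fix_acq
  cbf <- 55
  for (z in c(0L, 10L, 20L)) for (t1b in c(1.65, 1.47)) {
    dm <- cbf * 2 * acq$inv_eff * 1000 *
      quo2calib:::asl_kernel(t1b, acq$tau, slice_pld(z, acq)) /
      (6000 * acq$lam)
    expect_equal(cbf_quantify(dm, 1000, t1b, slice_index = z, acq = acq),
                 cbf, tolerance = 1e-9)
  }
})

test_that("delta R2* has the right sign, zero and antisymmetry", {
  expect_equal(delta_r2star(1, 1, 0.03), 0)
  expect_equal(delta_r2star(1.03, 1, 0.03), -0.985, tolerance = 1e-3)
  expect_equal(delta_r2star(0.97, 1, 0.03), 1.015, tolerance = 1e-3)
  expect_equal(delta_r2star(1.05, 1.01, 0.03),
               -delta_r2star(1.01, 1.05, 0.03), tolerance = 1e-12)
  expect_true(is.na(delta_r2star(-1, 1, 0.03)))
})

test_that("positive dR2* fraction counts exactly and flags empty masks", {
  dr2s <- array(-1, c(4, 4, 2))
  gm <- array(TRUE, c(4, 4, 2))
  expect_equal(positive_dr2s_fraction(dr2s, gm), 0)
  dr2s[1:4] <- 1   # 4 of 32
  expect_equal(positive_dr2s_fraction(dr2s, gm), 12.5)
  expect_error(positive_dr2s_fraction(dr2s, array(FALSE, c(4, 4, 2))),
               "empty")
  ## symmetric zero-mean noise: about half the voxels positive
  set.seed(5)
  noise <- array(rnorm(40 * 40 * 4), c(40, 40, 4))
  expect_lt(abs(positive_dr2s_fraction(noise, array(TRUE, dim(noise))) - 50),
            2)
})

test_that("response extraction round-trips a noiseless simulated subject", {
  par <- default_paradigm()
  p <- protocol_spec("LHO", sigma_trace = 0, transition_tau = 0)
  sc <- small_scene()
  resp <- forward_responses(sc, p)
  ts <- forward_timeseries(resp, small_acq, p, par)
  ex <- extract_responses(ts$echo1, ts$echo2, par, small_acq,
                          gas_from_protocol(p), gm = sc$gm, mask = sc$mask)
  i <- which(sc$mask)
  expect_lt(max(abs(ex$b_hc[i] - resp$b_hc[i])), 1e-6)
  expect_lt(max(abs(ex$b_ho[i] - resp$b_ho[i])), 1e-6)
  expect_lt(max(abs(ex$f_hc[i] - resp$f_hc[i]) / resp$f_hc[i]), 1e-6)
  expect_lt(max(abs(ex$cbf0[i] - sc$cbf0[i]) / sc$cbf0[i]), 1e-6)
  expect_equal(ex$f_ho_global, resp$f_ho_global, tolerance = 1e-3)
})

test_that("disabling the T1 correction reproduces the hyperoxia flow bias", {
  par <- default_paradigm()
  p <- protocol_spec("HHO", sigma_trace = 0, transition_tau = 0)
  sc <- small_scene()
  resp <- forward_responses(sc, p)
  ts <- forward_timeseries(resp, small_acq, p, par)
  gas <- gas_from_protocol(p)
  off <- extract_responses(ts$echo1, ts$echo2, par, small_acq, gas,
                           gm = sc$gm, mask = sc$mask, t1_correct = FALSE)
  on <- extract_responses(ts$echo1, ts$echo2, par, small_acq, gas,
                          gm = sc$gm, mask = sc$mask)
  ## true f_ho = 0.98; uncorrected is depressed by ~ the kernel ratio
  expect_equal(on$f_ho_global, 0.98, tolerance = 1e-3)
  expect_lt(off$f_ho_global, 0.87)
  fac <- mean(t1_correction_factor(1.65, blood_t1(654, fix_blood),
                                   acq = small_acq,
                                   pld = slice_pld(0:5, small_acq)))
  expect_equal(off$f_ho_global * fac, 0.98, tolerance = 5e-3)
})

test_that("volume count mismatch raises a paradigm misalignment error", {
  par <- default_paradigm()
  p <- protocol_spec("LHO", sigma_trace = 0, transition_tau = 0)
  sc <- small_scene()
  resp <- forward_responses(sc, p)
  ts <- forward_timeseries(resp, small_acq, p, par)
  short <- ts$echo1[, , , 1:100]
  expect_error(extract_responses(short, ts$echo2[, , , 1:100], par,
                                 small_acq, gas_from_protocol(p),
                                 gm = sc$gm, mask = sc$mask),
               "paradigm misalignment")
})
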