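test_that("generators are deterministic given a seed", {
  p <- protocol_spec("LHO", seed = 11)
  t1 <- simulate_gas_traces(p)
  t2 <- simulate_gas_traces(p)
  expect_identical(t1$co2$p, t2$co2$p)
  sc1 <- synth_scene(seed = 11)
  sc2 <- synth_scene(seed = 11)
  expect_identical(sc1$m, sc2$m)
  r1 <- forward_responses(sc1, p)
  r2 <- forward_responses(sc2, p)
  expect_identical(r1$b_hc, r2$b_hc)
  ## different seeds differ
  expect_false(identical(simulate_gas_traces(
    protocol_spec("LHO", seed = 12))$co2$p, t1$co2$p))
})

test_that("noiseless traces reproduce the protocol's epoch targets", {
  par <- default_paradigm()
  p <- protocol_spec("LHO", sigma_trace = 0, transition_tau = 0)
  tr <- simulate_gas_traces(p, par)
  g <- summarize_epochs(detect_end_tidal(tr$o2), detect_end_tidal(tr$co2),
                        par)
  expect_equal(g$eto2_0, 112, tolerance = 1e-9)
  expect_equal(g$eto2_ho, 369, tolerance = 1e-9)
  expect_equal(g$etco2_hc, 48, tolerance = 1e-9)
  expect_equal(g$detco2_ho, -1.0, tolerance = 1e-9)
})

test_that("noisy traces land near the protocol targets", {
  par <- default_paradigm()
  p <- protocol_spec("LHO", seed = 3)
  tr <- simulate_gas_traces(p, par)
  g <- summarize_epochs(detect_end_tidal(tr$o2), detect_end_tidal(tr$co2),
                        par)
  expect_lt(abs(g$eto2_ho - 369) / 369, 0.02)
  p2 <- protocol_spec("HHO", seed = 3)
  tr2 <- simulate_gas_traces(p2, par)
  g2 <- summarize_epochs(detect_end_tidal(tr2$o2), detect_end_tidal(tr2$co2),
                         par)
  expect_lt(abs(g2$eto2_ho - 654) / 654, 0.02)
})

test_that("breathing rate controls the end-tidal point density", {
  par <- default_paradigm()
  p <- protocol_spec("LHO", breath_rate = 6, sigma_trace = 0)
  tr <- simulate_gas_traces(p, par)
  et <- detect_end_tidal(tr$co2)
  rate <- length(et$et) / diff(range(et$breath_times)) * 60
  expect_lt(abs(rate - 6), 0.5)
})

test_that("the scene respects physiological ranges and geometry", {
  sc <- synth_scene(seed = 2)
  gm <- sc$tissue == 2L; wm <- sc$tissue == 1L
  expect_true(all(sc$m[gm | wm] >= 0.02 & sc$m[gm | wm] <= 0.12))
  expect_true(all(sc$oef[gm | wm] >= 0.25 & sc$oef[gm | wm] <= 0.50))
  expect_true(all(sc$cbf0[gm] >= 40 & sc$cbf0[gm] <= 70))
  expect_true(all(sc$cbf0[wm] >= 18 & sc$cbf0[wm] <= 30))
  ## tissue classes partition the brain mask; wedge is GM-only
  expect_true(all(sc$tissue[sc$mask] %in% 1:2))
  expect_true(all(sc$tissue[sc$wedge] == 2L))
  expect_equal(sum(sc$wedge) / sum(gm), 0.12, tolerance = 0.01)
})

test_that("forward responses match the hand-evaluated single voxel", {
  pair <- make_obs_pair()
  expect_equal(pair$hc$b, 0.015361, tolerance = 1e-4)
  expect_equal(pair$ho$b, 0.0121548, tolerance = 5e-4)
  ## and the generator agrees with the same forward model
  p <- protocol_spec("LHO", sigma_trace = 0)
  sc <- small_scene()
  resp <- forward_responses(sc, p)
  i <- which(sc$mask)[1:50]
  for (j in i) {
    f <- resp$f_hc[j]
    expect_equal(resp$b_hc[j],
                 forward_b(sc$m[j], sc$oef[j], f, fix_cao2_0),
                 tolerance = 1e-10)
  }
})

test_that("susceptibility injection hits the configured GM fraction", {
  sc <- synth_scene(dim = c(20, 20, 10), wedge_frac = 0.10, seed = 4)
  p <- protocol_spec("LHO", sigma_trace = 0)
  resp <- forward_responses(sc, p)
  gm_mask <- sc$tissue == 2L
  expect_equal(positive_dr2s_fraction(resp$dr2s_ho, gm_mask), 10,
               tolerance = 0.5)
  ## without injection nothing is positive in a noiseless run
  sc0 <- synth_scene(dim = c(20, 20, 10), wedge_frac = 0, seed = 4)
  resp0 <- forward_responses(sc0, p)
  expect_equal(positive_dr2s_fraction(resp0$dr2s_ho, sc0$tissue == 2L), 0)
})

test_that("time series have the expected volume count and determinism", {
  par <- default_paradigm()
  p <- protocol_spec("LHO", sigma_trace = 0)
  sc <- small_scene()
  resp <- forward_responses(sc, p)
  ts <- forward_timeseries(resp, small_acq, p, par)
  expect_equal(dim(ts$echo1)[4], floor(1080 / 4.12))
  ts2 <- forward_timeseries(resp, small_acq, p, par)
  expect_identical(ts$echo1, ts2$echo1)
})

test_that("the full pipeline is invariant to the hyperoxia level", {
  sc <- synth_scene(dim = c(16, 16, 8), seed = 6)
  maps <- lapply(c("LHO", "HHO"), function(nm) {
    p <- protocol_spec(nm, sigma_trace = 0)
    solve_maps(forward_responses(sc, p), gas_from_protocol(p))
  })
  both <- maps[[1]]$solved & maps[[2]]$solved
  expect_gt(mean(both[sc$mask & !sc$wedge]), 0.999)
  for (f in c("m", "oef", "cmro2")) {
    rel <- abs(maps[[1]][[f]][both] - maps[[2]][[f]][both]) /
      maps[[1]][[f]][both]
    expect_lt(max(rel), 0.001)
  }
})
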