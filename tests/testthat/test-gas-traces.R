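test_that("end-tidal detection recovers plateau values on clean breathing", {
  w <- breath_wave(60, 12, plateau = 40)
  et <- detect_end_tidal(gas_trace(w$t, w$p, "CO2"))
  expect_true(abs(length(et$et) - 12) <= 1)     # ~12 breaths/min
  expect_true(all(abs(et$et - 40) < 1e-9))

  ## one deviant breath: plateau 45 on breath 5 only
  plateau <- rep(40, length(w$t))
  plateau[w$t >= 4 * 5 & w$t < 5 * 5] <- 45
  w2 <- breath_wave(60, 12, plateau = plateau)
  et2 <- detect_end_tidal(gas_trace(w2$t, w2$p, "CO2"))
  expect_equal(sum(abs(et2$et - 45) < 1e-9), 1L)
  expect_true(all(abs(et2$et[abs(et2$et - 45) > 1e-9] - 40) < 1e-9))
})

test_that("breath count on drifting sinusoid matches brute-force maxima", {
  t <- seq(0, 300, by = 1 / 25)
  p <- 40 + 5 * sin(2 * pi * 0.25 * t) + 3 * sin(2 * pi * 0.01 * t)
  ## independent oracle: count strict local maxima of the waveform
  dp <- diff(p)
  n_max <- sum(dp[-length(dp)] > 0 & dp[-1L] < 0)
  et <- detect_end_tidal(gas_trace(t, p, "CO2"), smooth_window = 0)
  expect_true(abs(length(et$et) - n_max) <= 2)  # edge breaths may be partial
  expect_true(abs(length(et$et) - 0.25 * 300) <= 1)
})

test_that("flat or too-short traces raise 'no breaths detected'", {
  t <- seq(0, 60, by = 0.04)
  expect_error(detect_end_tidal(gas_trace(t, rep(40, length(t)), "CO2")),
               "no breaths detected")
  w <- breath_wave(3, 12, 40)
  expect_error(detect_end_tidal(gas_trace(w$t, w$p, "CO2")),
               "no breaths detected")
})

test_that("detection requires adequate sampling and merges close breaths", {
  w <- breath_wave(60, 12, 40, sample_rate = 2)
  expect_error(detect_end_tidal(gas_trace(w$t, w$p, "CO2")), "4 Hz")
  ## a large min_breath_period merges every pair of 5-s breaths
  w2 <- breath_wave(120, 12, 40)
  et <- detect_end_tidal(gas_trace(w2$t, w2$p, "CO2"), min_breath_period = 8)
  expect_true(all(diff(et$breath_times) >= 8))
})

test_that("end-tidal correction applies gain and water-vapor conversion", {
  expect_equal(correct_end_tidal(0.05, filter_gain = 1,
                                 barometric_pressure = 760,
                                 input_is_dry_fraction = TRUE),
               0.05 * 713, tolerance = 1e-12)
  expect_equal(correct_end_tidal(c(35, 40, 45)), c(35, 40, 45))
  expect_equal(correct_end_tidal(38, filter_gain = 0.95), 40, tolerance = 1e-9)
  expect_error(correct_end_tidal(38, filter_gain = 0), "configuration error")
  ## linearity and monotonicity in the input
  x <- c(10, 20, 40)
  y <- correct_end_tidal(x, filter_gain = 0.9)
  expect_equal(y, x / 0.9)
  expect_true(all(diff(y) > 0))
  ets <- end_tidal_series(1:3, c(38, 39, 40), "CO2")
  expect_s3_class(correct_end_tidal(ets, 0.95), "end_tidal_series")
})

test_that("epoch summaries average the configured steady-state windows", {
  par <- default_paradigm()
  ## piecewise-constant end-tidal series at the epoch targets
  bt <- seq(5, 1075, by = 7.5)
  lab <- par$label[findInterval(bt, par$start)]
  o2 <- ifelse(lab == "HO", 369, 112)
  co2 <- ifelse(lab == "HC", 48, 40)
  g <- summarize_epochs(end_tidal_series(bt, o2, "O2"),
                        end_tidal_series(bt, co2, "CO2"), par)
  expect_equal(g$eto2_0, 112)
  expect_equal(g$eto2_ho, 369)
  expect_equal(g$etco2_hc, 48)
  expect_equal(g$detco2_hc, 8)

  ## a 60-s linear ramp into the HC plateau is excluded by the late window
  co2_ramp <- co2
  for (i in which(par$label == "HC")) {
    sel <- bt >= par$start[i] & bt < par$start[i] + 60
    co2_ramp[sel] <- 40 + 8 * (bt[sel] - par$start[i]) / 60
  }
  g2 <- summarize_epochs(end_tidal_series(bt, o2, "O2"),
                         end_tidal_series(bt, co2_ramp, "CO2"), par)
  expect_equal(g2$etco2_hc, 48)

  ## empty window errors
  few <- end_tidal_series(c(1, 2), c(40, 40), "CO2")
  expect_error(summarize_epochs(end_tidal_series(c(1, 2), c(112, 112), "O2"),
                                few, par),
               "empty epoch window")
})

test_that("epoch means are invariant to trace resampling (4 vs 25 Hz)", {
  par <- default_paradigm()
  g_at <- function(sr) {
    p <- protocol_spec("LHO", sigma_trace = 0, sample_rate = sr)
    tr <- simulate_gas_traces(p, par)
    summarize_epochs(detect_end_tidal(tr$o2), detect_end_tidal(tr$co2), par)
  }
  g4 <- g_at(4); g25 <- g_at(25)
  for (f in c("eto2_0", "eto2_ho", "etco2_0", "etco2_hc", "etco2_ho"))
    expect_lt(abs(g4[[f]] - g25[[f]]), 0.5)
})

test_that("epoch means are unbiased under additive trace noise", {
  par <- default_paradigm()
  sigma <- 1
  set.seed(101)
  sims <- replicate(40, {
    p <- protocol_spec("LHO", sigma_trace = sigma, transition_tau = 0,
                       seed = sample.int(1e6, 1))
    tr <- simulate_gas_traces(p, par)
    g <- summarize_epochs(detect_end_tidal(tr$o2),
                          detect_end_tidal(tr$co2), par)
    c(g$eto2_0, g$eto2_ho)
  })
  ## ~24 baseline and ~32 hyperoxia breaths contribute per run
  expect_lt(abs(mean(sims[1, ]) - 112), 3 * sigma / sqrt(24))
  expect_lt(abs(mean(sims[2, ]) - 369), 3 * sigma / sqrt(32))
})

test_that("gas trace files round-trip through the reader", {
  w <- breath_wave(30, 10, 40)
  p2 <- file.path(tempdir(), "co2.csv")
  writeLines(c("# BIOPAC export", "time_s,co2",
               paste(w$t, w$p, sep = ",")), p2)
  tr <- read_gas_trace(p2, gas = "CO2")
  expect_s3_class(tr, "gas_trace")
  expect_equal(tr$p, w$p)
  p3 <- file.path(tempdir(), "both.tsv")
  writeLines(c("time_s\to2\tco2",
               paste(w$t, 112, w$p, sep = "\t")), p3)
  both <- read_gas_trace(p3)
  expect_equal(both$o2$gas, "O2")
  expect_equal(both$co2$p, w$p)
})

test_that("paradigm validation and file round trip work", {
  expect_error(paradigm("HC", 10, 5), "end > start")
  expect_error(paradigm(c("HC", "HO"), c(0, 130), c(120, 300)), "contiguous")
  par <- default_paradigm()
  expect_equal(max(par$end), 1080)
  expect_equal(sum(par$label == "HC"), 2L)
  expect_equal(par$end[par$label == "HC"] - par$start[par$label == "HC"],
               c(120, 120))
  expect_equal(par$end[par$label == "HO"] - par$start[par$label == "HO"],
               c(180, 180))
  pth <- file.path(tempdir(), "paradigm.yaml")
  yaml::write_yaml(lapply(seq_len(nrow(par)), function(i)
    list(label = par$label[i], start = par$start[i], end = par$end[i])), pth)
  expect_equal(paradigm_from_file(pth)$end, par$end)
})
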