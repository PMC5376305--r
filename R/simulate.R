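#' Hyperoxia protocol specification
#'
#' Encodes the gas targets and noise levels of one inspired-O2 protocol. The
#' two named presets follow the study design this package emulates: `LHO`
#' (60% inspired O2; hyperoxic end-tidal O2 near 369 mmHg, hyperoxic ETCO2
#' drop -1.0 mmHg) and `HHO` (100% O2; 654 mmHg, -2.4 mmHg). Baseline
#' end-tidal O2 is 112 mmHg and baseline ETCO2 40 mmHg; hypercapnia raises
#' ETCO2 by `detco2_hc` (default +8 mmHg, typical of 5% inspired CO2).
#'
#' @param name `"LHO"` or `"HHO"` (sets `eto2_ho`, `fio2` and `detco2_ho`
#'   defaults).
#' @param eto2_0,eto2_ho baseline / hyperoxic end-tidal O2 targets, mmHg.
#' @param etco2_0 baseline end-tidal CO2, mmHg.
#' @param detco2_hc,detco2_ho ETCO2 change during hypercapnia / hyperoxia,
#'   mmHg.
#' @param fio2 inspired O2 fraction during hyperoxia.
#' @param breath_rate breaths per minute.
#' @param sample_rate trace sampling rate, Hz.
#' @param transition_tau exponential time constant of end-tidal transitions
#'   between epochs, seconds (0 = instantaneous).
#' @param sigma_trace additive Gaussian noise on the gas traces, mmHg.
#' @param sigma_b,sigma_f additive Gaussian noise on voxelwise BOLD fractions
#'   and CBF ratios.
#' @param sigma_ts additive Gaussian thermal noise on simulated time series,
#'   in signal units.
#' @param seed RNG seed recorded with the protocol.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(name = c("LHO", "HHO"), eto2_0 = 112,
                          eto2_ho = NULL, etco2_0 = 40, detco2_hc = 8,
                          detco2_ho = NULL, fio2 = NULL, breath_rate = 8,
                          sample_rate = 25, transition_tau = 20,
                          sigma_trace = 1, sigma_b = 0, sigma_f = 0,
                          sigma_ts = 0, seed = 1L) {
  name <- match.arg(name)
  eto2_ho <- eto2_ho %||% switch(name, LHO = 369, HHO = 654)
  detco2_ho <- detco2_ho %||% switch(name, LHO = -1.0, HHO = -2.4)
  fio2 <- fio2 %||% switch(name, LHO = 0.60, HHO = 1.00)
  if (eto2_ho <= eto2_0)
    stop_quo2("protocol_spec: hyperoxic ETO2 must exceed baseline")
  check_number(breath_rate, "breath_rate", lower = 1)
  check_number(transition_tau, "transition_tau", lower = 0)
  structure(list(name = name, eto2_0 = eto2_0, eto2_ho = eto2_ho,
                 etco2_0 = etco2_0, detco2_hc = detco2_hc,
                 detco2_ho = detco2_ho, fio2 = fio2,
                 breath_rate = breath_rate, sample_rate = sample_rate,
                 transition_tau = transition_tau, sigma_trace = sigma_trace,
                 sigma_b = sigma_b, sigma_f = sigma_f, sigma_ts = sigma_ts,
                 seed = seed),
            class = "protocol_spec")
}

#' Epoch gas summary implied by a protocol's targets
#'
#' @param protocol a [protocol_spec()].
#' @return An [epoch_gas_summary()] at the protocol's nominal end-tidal
#'   targets (hypercapnia leaves ETO2 at baseline).
#' @export
gas_from_protocol <- function(protocol) {
  epoch_gas_summary(
    eto2_0 = protocol$eto2_0, etco2_0 = protocol$etco2_0,
    eto2_hc = protocol$eto2_0,
    etco2_hc = protocol$etco2_0 + protocol$detco2_hc,
    eto2_ho = protocol$eto2_ho,
    etco2_ho = protocol$etco2_0 + protocol$detco2_ho)
}

## epoch-target level curve with exponential transitions, evaluated at t
level_curve <- function(t, par, targets, tau) {
  lev <- numeric(length(t))
  cur <- targets[["baseline"]]
  for (i in seq_len(nrow(par))) {
    tgt <- targets[[par$label[i]]] %||% targets[["baseline"]]
    sel <- t >= par$start[i] & t < par$end[i] + 1e-12
    lev[sel] <- if (tau <= 0) tgt
    else tgt + (cur - tgt) * exp(-(t[sel] - par$start[i]) / tau)
    cur <- if (tau <= 0) tgt
    else tgt + (cur - tgt) * exp(-(par$end[i] - par$start[i]) / tau)
  }
  lev
}

## smooth expiratory weight over breath phase in [0,1): 0 during inspiration,
## 1 on the expiratory plateau (second half of the cycle)
breath_weight <- function(phase) {
  w <- numeric(length(phase))
  ramp <- phase >= 0.35 & phase < 0.5
  w[ramp] <- (1 - cos(pi * (phase[ramp] - 0.35) / 0.15)) / 2
  w[phase >= 0.5] <- 1
  w
}

#' Simulate respiratory O2 and CO2 traces
#'
#' Generates breath-by-breath partial-pressure traces whose expiratory
#' plateaus follow the protocol's epoch targets with exponential transitions,
#' plus additive Gaussian noise. The CO2 trace oscillates between an
#' inspiratory dead-space level (~2 mmHg) and the end-tidal target; the O2
#' trace between the inspired partial pressure (humidified: fio2 x
#' (760 - 47) mmHg during hyperoxia, air otherwise) and the end-tidal target.
#'
#' @param protocol a [protocol_spec()].
#' @param par a [paradigm()].
#' @param seed RNG seed; defaults to the protocol's.
#' @return `list(o2 = , co2 = )` of [gas_trace()] objects.
#' @export
simulate_gas_traces <- function(protocol, par = default_paradigm(),
                                seed = protocol$seed) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(par, "paradigm"))
  with_seed(seed, {
    dt <- 1 / protocol$sample_rate
    t <- seq(0, max(par$end) - dt, by = dt)
    tau <- protocol$transition_tau
    co2_lev <- level_curve(t, par, list(
      baseline = protocol$etco2_0,
      HC = protocol$etco2_0 + protocol$detco2_hc,
      HO = protocol$etco2_0 + protocol$detco2_ho,
      recovery = protocol$etco2_0), tau)
    o2_lev <- level_curve(t, par, list(
      baseline = protocol$eto2_0, HC = protocol$eto2_0,
      HO = protocol$eto2_ho, recovery = protocol$eto2_0), tau)
    insp_o2_air <- 0.2095 * (760 - 47)
    insp_o2 <- ifelse(
      par$label[pmin(findInterval(t, par$start), nrow(par))] == "HO",
      protocol$fio2 * (760 - 47), insp_o2_air)
    period <- 60 / protocol$breath_rate
    w <- breath_weight((t %% period) / period)
    co2 <- 2 + (co2_lev - 2) * w
    o2 <- insp_o2 - (insp_o2 - o2_lev) * w
    if (protocol$sigma_trace > 0) {
      co2 <- pmax(co2 + stats::rnorm(length(t), 0, protocol$sigma_trace), 0)
      o2 <- pmax(o2 + stats::rnorm(length(t), 0, protocol$sigma_trace), 0)
    }
    list(o2 = gas_trace(t, o2, gas = "O2",
                        sample_rate = protocol$sample_rate),
         co2 = gas_trace(t, co2, gas = "CO2",
                         sample_rate = protocol$sample_rate))
  })
}

#' Synthetic ground-truth scene
#'
#' Builds a 3D digital phantom: an ellipsoidal brain with a white-matter core,
#' a gray-matter shell and an optional anterior "paranasal" wedge (a fixed
#' fraction of GM voxels, restricted to the lower slices) that will receive a
#' positive-dR2* susceptibility artifact. Voxelwise ground-truth fields are
#' drawn per tissue: M in 0.02-0.12, OEF in 0.25-0.50, baseline CBF 40-70
#' (GM) / 18-30 (WM) ml/100g/min, deterministically for a given seed.
#'
#' @param dim 3D grid size (default 32 x 32 x 21, mimicking 21 slices).
#' @param wedge_frac fraction of GM voxels assigned to the susceptibility
#'   wedge (default 0.12; 0 disables it).
#' @param seed RNG seed.
#' @return An object of class `ground_truth` with arrays `m`, `oef`, `cbf0`,
#'   `tissue` (0 background, 1 WM, 2 GM), `gm` (probability), `wedge`
#'   (logical) and `mask`.
#' @export
synth_scene <- function(dim = c(32, 32, 21), wedge_frac = 0.12, seed = 1L) {
  stopifnot(length(dim) == 3L)
  with_seed(seed, {
    nx <- dim[1L]; ny <- dim[2L]; nz <- dim[3L]
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
    x <- slice.index(array(0, dim), 1L)
    y <- slice.index(array(0, dim), 2L)
    z <- slice.index(array(0, dim), 3L)
    ## ellipsoidal radius normalized to 1 at the brain edge
    r <- sqrt(((x - cx) / (0.44 * nx))^2 + ((y - cy) / (0.44 * ny))^2 +
                ((z - cz) / (0.62 * nz))^2)
    tissue <- array(0L, dim)
    tissue[r < 1] <- 2L                    # GM shell
    tissue[r < 0.62] <- 1L                 # WM core
    mask <- tissue > 0L

    gm_idx <- which(tissue == 2L)
    n_wedge <- round(wedge_frac * length(gm_idx))
    wedge <- array(FALSE, dim)
    if (n_wedge > 0L) {
      low <- z[gm_idx] <= ceiling(nz / 3)
      cand <- gm_idx[order(!low, y[gm_idx])]   # anterior, lower slices first
      wedge[cand[seq_len(min(n_wedge, length(cand)))]] <- TRUE
    }

    draw <- function(idx, mean, sd, lo, hi) {
      v <- stats::rnorm(length(idx), mean, sd)
      pmin(pmax(v, lo), hi)
    }
    m <- oef <- cbf0 <- array(NA_real_, dim)
    wm_idx <- which(tissue == 1L)
    m[gm_idx] <- draw(gm_idx, 0.06, 0.012, 0.02, 0.12)
    m[wm_idx] <- draw(wm_idx, 0.035, 0.006, 0.02, 0.12)
    oef[gm_idx] <- draw(gm_idx, 0.35, 0.04, 0.25, 0.50)
    oef[wm_idx] <- draw(wm_idx, 0.35, 0.04, 0.25, 0.50)
    cbf0[gm_idx] <- draw(gm_idx, 55, 7, 40, 70)
    cbf0[wm_idx] <- draw(wm_idx, 24, 3, 18, 30)

    gm <- array(0, dim)
    gm[gm_idx] <- pmin(pmax(stats::rnorm(length(gm_idx), 0.85, 0.08),
                            0.55), 1)
    gm[wm_idx] <- pmin(pmax(stats::rnorm(length(wm_idx), 0.15, 0.08),
                            0), 0.45)
    structure(list(m = m, oef = oef, cbf0 = cbf0, tissue = tissue, gm = gm,
                   wedge = wedge, mask = mask, dim = dim, seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground-truth scene %s: %d GM, %d WM voxels, wedge %d voxels\n",
    paste(x$dim, collapse = "x"), sum(x$tissue == 2L), sum(x$tissue == 1L),
    sum(x$wedge)))
  invisible(x)
}

#' Forward-simulate epoch responses from ground truth
#'
#' Applies the calibrated-BOLD forward equation at each voxel's true (M, OEF):
#' the hypercapnic CBF ratio comes from a CO2 reactivity model (percent flow
#' change per mmHg ETCO2, scaled per tissue), the hyperoxic CBF ratio is a
#' uniform mild vasoconstriction, and the BOLD fractions follow
#' b = M (1 - f^alpha r^beta). The hyperoxia dR2* map is -log(1 + b_ho)/te2;
#' inside the susceptibility wedge a positive dR2* offset is injected and the
#' wedge's b_ho is made consistent with it (which renders those voxels
#' unsolvable, as around real air cavities). Gaussian noise is added per the
#' protocol's sigma values.
#'
#' @param truth a [synth_scene()].
#' @param protocol a [protocol_spec()].
#' @param bold,blood model settings.
#' @param vascular list: `reactivity_gm`, `reactivity_wm` (fractional CBF
#'   change per mmHg ETCO2), `f_ho` (true hyperoxic CBF ratio),
#'   `wedge_dr2s` (injected artifact dR2*, 1/s).
#' @param te2 BOLD echo time used for the dR2* diagnostic, s.
#' @param seed RNG seed; defaults to the protocol's.
#' @return A [response_set()]; the ground truth travels in `$extras$truth`.
#' @export
forward_responses <- function(truth, protocol, bold = bold_model(),
                              blood = blood_model(),
                              vascular = list(reactivity_gm = 0.03,
                                              reactivity_wm = 0.015,
                                              f_ho = 0.98,
                                              wedge_dr2s = 2),
                              te2 = 0.030, seed = protocol$seed) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(protocol, "protocol_spec"))
  with_seed(seed, {
    gas <- gas_from_protocol(protocol)
    cao2_0 <- arterial_o2_content(gas$eto2_0, blood)
    cao2_hc <- arterial_o2_content(gas$eto2_hc, blood)
    cao2_ho <- arterial_o2_content(gas$eto2_ho, blood)
    cap <- blood$phi * blood$hb / 100
    d <- truth$dim
    idx <- which(truth$mask)

    react <- ifelse(truth$tissue[idx] == 2L, vascular$reactivity_gm,
                    vascular$reactivity_wm)
    f_hc <- 1 + react * gas$detco2_hc
    f_ho <- vascular$f_ho

    fwd_b <- function(f, cao2) {
      r <- dhb_ratio_core(truth$oef[idx], f, cao2, cao2_0, cap)$r
      truth$m[idx] * (1 - f^bold$alpha * r^bold$beta)
    }
    b_hc <- fwd_b(f_hc, cao2_hc)
    b_ho <- fwd_b(f_ho, cao2_ho)

    dr2s <- -log(1 + b_ho) / te2
    wsel <- truth$wedge[idx]
    if (any(wsel)) {
      dr2s[wsel] <- dr2s[wsel] + vascular$wedge_dr2s
      b_ho[wsel] <- exp(-te2 * dr2s[wsel]) - 1   # artifact-consistent BOLD
    }

    n <- length(idx)
    if (protocol$sigma_b > 0) {
      b_hc <- b_hc + stats::rnorm(n, 0, protocol$sigma_b)
      b_ho <- b_ho + stats::rnorm(n, 0, protocol$sigma_b)
    }
    if (protocol$sigma_f > 0)
      f_hc <- pmax(f_hc + stats::rnorm(n, 0, protocol$sigma_f), 1e-3)

    shape <- function(v, fill = NA_real_) {
      a <- array(fill, d); a[idx] <- v; a
    }
    response_set(shape(b_hc), shape(b_ho), shape(f_hc), f_ho,
                 truth$cbf0, shape(dr2s), truth$mask, truth$gm,
                 extras = list(truth = truth, protocol = protocol,
                               gas = gas, f_hc_true = shape(f_hc),
                               vascular = vascular))
  })
}

#' Forward-simulate 4D dual-echo pCASL series
#'
#' Synthesizes control/label-alternating echo-1 and echo-2 volumes at the
#' acquisition TR over the paradigm. The echo-1 perfusion-weighted difference
#' follows the single-compartment quantitative flow equation with the
#' slice-dependent PLD and the epoch-appropriate arterial blood T1 — so the
#' hyperoxia T1-shortening bias is present in the raw data exactly as it
#' would be in vivo. Echo-2 control volumes carry the BOLD modulation
#' (1 + b(t)). Gaussian thermal noise is added per `protocol$sigma_ts`.
#'
#' @param responses a [response_set()] from [forward_responses()].
#' @param acq an [acq_params()].
#' @param protocol a [protocol_spec()].
#' @param par a [paradigm()].
#' @param blood a [blood_model()].
#' @param m0 equilibrium signal level (scalar or 3D array).
#' @param control_first `TRUE` when volume 1 is a control image.
#' @param seed RNG seed; defaults to the protocol's.
#' @return `list(echo1, echo2, times, control_first, acq)`, the series as 4D
#'   arrays.
#' @export
forward_timeseries <- function(responses, acq = acq_params(), protocol,
                               par = default_paradigm(),
                               blood = blood_model(), m0 = 1000,
                               control_first = TRUE,
                               seed = protocol$seed) {
  stopifnot(inherits(responses, "response_set"))
  d <- responses$dim
  if (d[3L] != acq$n_slices)
    stop_quo2("forward_timeseries: scene has %d slices but acq expects %d",
              d[3L], acq$n_slices)
  with_seed(seed, {
    nvol <- floor(max(par$end) / acq$tr)
    times <- (seq_len(nvol) - 1L) * acq$tr
    lab_of <- par$label[pmin(findInterval(times, par$start), nrow(par))]

    nvox <- prod(d[1:3])
    m0a <- if (length(m0) == 1L) array(m0, d[1:3]) else m0
    zidx <- rep(seq_len(d[3L]) - 1L, each = d[1L] * d[2L])
    pld <- slice_pld(zidx, acq)

    f_of <- function(lab) switch(lab, HC = responses$f_hc,
                                 HO = array(responses$f_ho_global, d[1:3]),
                                 array(1, d[1:3]))
    b_of <- function(lab) switch(lab, HC = responses$b_hc,
                                 HO = responses$b_ho, array(0, d[1:3]))
    t1_of <- function(lab) {
      if (lab == "HO")
        blood_t1(responses$extras$gas$eto2_ho %||%
                   gas_from_protocol(protocol)$eto2_ho, blood)
      else blood$t1_ref
    }

    e1 <- matrix(0, nvox, nvol)
    e2 <- matrix(0, nvox, nvol)
    cbf0v <- responses$cbf0
    cbf0v[!responses$mask | !is.finite(cbf0v)] <- 0
    is_ctrl <- rep(c(control_first, !control_first), length.out = nvol)
    for (v in seq_len(nvol)) {
      lab <- lab_of[v]
      fv <- f_of(lab); bv <- b_of(lab)
      fv[!responses$mask] <- 1
      bv[!is.finite(bv)] <- 0
      dm <- cbf0v * as.numeric(fv) * 2 * acq$inv_eff * m0a *
        asl_kernel(t1_of(lab), acq$tau, pld) / (6000 * acq$lam)
      e1[, v] <- if (is_ctrl[v]) m0a else m0a - dm
      bold <- m0a * (1 + as.numeric(bv))
      e2[, v] <- if (is_ctrl[v]) bold else bold - dm
    }
    if (protocol$sigma_ts > 0) {
      e1 <- e1 + stats::rnorm(length(e1), 0, protocol$sigma_ts)
      e2 <- e2 + stats::rnorm(length(e2), 0, protocol$sigma_ts)
    }
    list(echo1 = array(e1, c(d[1:3], nvol)),
         echo2 = array(e2, c(d[1:3], nvol)),
         times = times, control_first = control_first, acq = acq)
  })
}
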