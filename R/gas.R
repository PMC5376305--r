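#' Respiratory gas trace
#'
#' Container for a continuously sampled O2 or CO2 partial-pressure trace
#' (or dry gas fraction, see [correct_end_tidal()]).
#'
#' @param t sample times in seconds, monotone non-decreasing.
#' @param p partial-pressure samples, mmHg (all >= 0), or dry fractions.
#' @param gas `"O2"` or `"CO2"`.
#' @param sample_rate sampling rate in Hz; inferred from `t` when `NULL`.
#' @return An object of class `gas_trace`.
#' @export
gas_trace <- function(t, p, gas = c("CO2", "O2"), sample_rate = NULL) {
  gas <- match.arg(gas)
  if (length(t) != length(p))
    stop_quo2("gas_trace: t and p must have equal length")
  if (length(t) < 2L || is.unsorted(t))
    stop_quo2("gas_trace: t must be monotone non-decreasing, length >= 2")
  if (any(!is.finite(p)) || any(p < 0))
    stop_quo2("gas_trace: p must be finite and non-negative")
  if (is.null(sample_rate))
    sample_rate <- 1 / stats::median(diff(t))
  check_number(sample_rate, "sample_rate", lower = 1e-9)
  structure(list(t = as.numeric(t), p = as.numeric(p), gas = gas,
                 sample_rate = sample_rate),
            class = "gas_trace")
}

#' @export
print.gas_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d samples at %.3g Hz, %.1f-%.1f s, range %.1f-%.1f\n",
              x$gas, length(x$p), x$sample_rate, min(x$t), max(x$t),
              min(x$p), max(x$p)))
  invisible(x)
}

#' Read a physiological gas trace from CSV/TSV
#'
#' Accepts two-column files (`time_s`, value) for a single gas or three-column
#' files (`time_s`, `o2`, `co2`). Comment lines starting with `#` (as in
#' BIOPAC-style exports) are skipped; a header row is required. Whether values
#' are mmHg or dry fractions is declared downstream via [correct_end_tidal()].
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise
#'   comma-separated.
#' @param gas gas label used when the file has a single value column.
#' @return A `gas_trace`, or a named list `list(o2 = , co2 = )` for
#'   three-column files.
#' @export
read_gas_trace <- function(path, gas = c("CO2", "O2")) {
  gas <- match.arg(gas)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         strip.white = TRUE)
  if (ncol(d) == 2L) {
    gas_trace(d[[1L]], d[[2L]], gas = gas)
  } else if (ncol(d) == 3L) {
    nm <- tolower(names(d))
    io2 <- which(grepl("o2", nm) & !grepl("co2", nm))[1L]
    ico2 <- which(grepl("co2", nm))[1L]
    if (is.na(io2) || is.na(ico2))
      stop_quo2("read_gas_trace: cannot identify o2/co2 columns in '%s'", path)
    list(o2 = gas_trace(d[[1L]], d[[io2]], gas = "O2"),
         co2 = gas_trace(d[[1L]], d[[ico2]], gas = "CO2"))
  } else {
    stop_quo2("read_gas_trace: expected 2 or 3 columns, got %d", ncol(d))
  }
}

#' Respiratory block paradigm
#'
#' @param label block labels among `baseline`, `HC`, `HO`, `recovery`.
#' @param start,end block boundaries in seconds; blocks must be contiguous and
#'   non-overlapping.
#' @return A `paradigm` data frame.
#' @seealso [default_paradigm()]
#' @export
paradigm <- function(label, start, end) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  if (!all(label %in% c("baseline", "HC", "HO", "recovery")))
    stop_quo2("paradigm: labels must be baseline/HC/HO/recovery")
  o <- order(start)
  label <- label[o]; start <- start[o]; end <- end[o]
  if (any(end <= start))
    stop_quo2("paradigm: each block needs end > start")
  if (length(start) > 1L && any(abs(start[-1L] - end[-length(end)]) > 1e-9))
    stop_quo2("paradigm: blocks must be contiguous and non-overlapping")
  structure(data.frame(label = label, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("paradigm", "data.frame"))
}

#' Default 18-minute gas paradigm
#'
#' Two cycles of: 2-min hypercapnia, 1-min normocapnia, 3-min hyperoxia,
#' 3-min normoxia (each cycle 9 min; total 1080 s).
#'
#' @return A `paradigm`.
#' @export
default_paradigm <- function() {
  one <- data.frame(label = c("HC", "baseline", "HO", "baseline"),
                    dur = c(120, 60, 180, 180))
  lab <- rep(one$label, 2L)
  dur <- rep(one$dur, 2L)
  end <- cumsum(dur)
  paradigm(lab, c(0, end[-length(end)]), end)
}

#' Read a paradigm from YAML or JSON
#'
#' Expects a list of blocks, each with `label`, `start`, `end` in seconds.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A `paradigm`.
#' @export
paradigm_from_file <- function(path) {
  blocks <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  paradigm(vapply(blocks, `[[`, "", "label"),
           vapply(blocks, function(b) as.numeric(b$start), 0),
           vapply(blocks, function(b) as.numeric(b$end), 0))
}

#' End-tidal series
#'
#' One corrected or raw end-tidal value per detected breath.
#'
#' @param breath_times strictly increasing breath times, seconds.
#' @param et end-tidal values per breath.
#' @param gas `"O2"` or `"CO2"`.
#' @return An object of class `end_tidal_series`.
#' @export
end_tidal_series <- function(breath_times, et, gas = c("CO2", "O2")) {
  gas <- match.arg(gas)
  stopifnot(length(breath_times) == length(et))
  if (length(breath_times) > 1L && any(diff(breath_times) <= 0))
    stop_quo2("end_tidal_series: breath_times must be strictly increasing")
  structure(list(breath_times = as.numeric(breath_times),
                 et = as.numeric(et), gas = gas),
            class = "end_tidal_series")
}

#' @export
print.end_tidal_series <- function(x, ...) {
  cat(sprintf("End-tidal %s: %d breaths over %.0f s, median %.1f\n",
              x$gas, length(x$et), diff(range(x$breath_times)),
              stats::median(x$et)))
  invisible(x)
}

#' Detect end-tidal points on a gas trace
#'
#' Breaths are delimited by zero-crossings of the trace after removal of a
#' centered rolling-mean baseline (window `detrend_window` seconds): upward
#' crossings for CO2, downward for O2, so that one crossing falls in each
#' respiratory cycle. The end-tidal value is the per-breath expiratory maximum
#' for CO2 and expiratory minimum for O2. Candidate breaths closer than
#' `min_breath_period` are merged, keeping the more extreme value.
#'
#' For paired O2/CO2 recordings the CO2 oscillation is the more robust
#' respiratory clock; pass its crossing times through `boundaries` to segment
#' the O2 trace on the same breaths.
#'
#' @param trace a [gas_trace()], sampled at >= 4 Hz and covering >= 2 breaths.
#' @param min_breath_period minimum breath period in seconds (default 2 s,
#'   a safe lower bound for resting rates of 6-12 breaths/min).
#' @param detrend_window baseline-removal window, seconds.
#' @param noise_floor minimum peak-to-peak oscillation (same units as the
#'   trace) below which no breaths are declared.
#' @param smooth_window light pre-smoothing window (seconds) applied before
#'   extremum picking; suppresses the upward/downward bias that taking a raw
#'   per-breath max/min of noisy samples would create. Must be shorter than
#'   the expiratory plateau so noiseless plateau values are preserved.
#' @param boundaries optional vector of breath-boundary times (seconds)
#'   taken from another trace.
#' @return An [end_tidal_series()].
#' @export
detect_end_tidal <- function(trace, min_breath_period = 2,
                             detrend_window = 15, noise_floor = 1,
                             smooth_window = 1, boundaries = NULL) {
  stopifnot(inherits(trace, "gas_trace"))
  check_number(min_breath_period, "min_breath_period", lower = 1e-6)
  if (trace$sample_rate < 4)
    stop_quo2("detect_end_tidal: sample_rate must be >= 4 Hz")
  if (diff(range(trace$t)) < 2 * min_breath_period)
    stop_quo2("no breaths detected: trace shorter than two breath periods")
  p_sm <- if (smooth_window > 0)
    roll_mean(trace$p, smooth_window * trace$sample_rate)
  else trace$p
  x <- p_sm - roll_mean(p_sm, detrend_window * trace$sample_rate)
  if (diff(range(x)) < noise_floor)
    stop_quo2("no breaths detected: no oscillation above the noise floor")

  if (is.null(boundaries)) {
    s <- sign(x)
    s[s == 0] <- 1
    idx <- if (trace$gas == "CO2") which(diff(s) > 0) else which(diff(s) < 0)
    if (length(idx) < 2L)
      stop_quo2("no breaths detected: fewer than two respiratory cycles")
    boundaries <- trace$t[idx + 1L]
  }
  boundaries <- sort(boundaries)
  seg <- findInterval(trace$t, boundaries)
  keep <- seg >= 1L & seg < length(boundaries)   # complete breaths only
  if (!any(keep))
    stop_quo2("no breaths detected: no complete breath within boundaries")
  pick <- if (trace$gas == "CO2") which.max else which.min
  ## an expiratory plateau extremum is interior to its breath segment; an
  ## extremum sitting on a segment edge is a transition artifact, not a breath
  guard <- max(2L, round(smooth_window * trace$sample_rate / 2))
  bt <- et <- numeric(0)
  for (g in split(which(keep), seg[keep])) {
    k <- pick(p_sm[g])
    if (length(g) > 2L * guard && (k <= guard || k > length(g) - guard))
      next
    j <- g[k]
    bt <- c(bt, trace$t[j]); et <- c(et, p_sm[j])
  }
  if (length(bt) < 2L)
    stop_quo2("no breaths detected: fewer than two usable breaths")
  ## merge breaths closer than the minimum breath period
  better <- if (trace$gas == "CO2") `>=` else `<=`
  i <- 2L
  while (i <= length(bt)) {
    if (bt[i] - bt[i - 1L] < min_breath_period) {
      keep_i <- if (better(et[i], et[i - 1L])) i else i - 1L
      drop_i <- if (keep_i == i) i - 1L else i
      bt <- bt[-drop_i]; et <- et[-drop_i]
    } else i <- i + 1L
  }
  end_tidal_series(bt, et, gas = trace$gas)
}

#' Correct end-tidal values for sampling-line filtering and water vapor
#'
#' Divides by the multiplicative low-pass gain of the in-line filter and, when
#' the input is a dry gas fraction, converts to partial pressure against the
#' water-vapor-corrected barometric pressure:
#' p = fraction * (P_B - 47 mmHg).
#'
#' @param et an [end_tidal_series()] or numeric vector.
#' @param filter_gain filter gain in (0, 1]; 1 means no attenuation.
#' @param barometric_pressure barometric pressure, mmHg (> 47).
#' @param input_is_dry_fraction set `TRUE` when `et` holds dry fractions.
#' @return Same class as `et`, corrected.
#' @export
correct_end_tidal <- function(et, filter_gain = 1, barometric_pressure = 760,
                              input_is_dry_fraction = FALSE) {
  if (!is.numeric(filter_gain) || length(filter_gain) != 1L ||
      !is.finite(filter_gain) || filter_gain <= 0 || filter_gain > 1)
    stop_quo2("configuration error: filter_gain must be in (0, 1]")
  check_number(barometric_pressure, "barometric_pressure", lower = 47 + 1e-9)
  vals <- if (inherits(et, "end_tidal_series")) et$et else et
  if (input_is_dry_fraction)
    vals <- vals * (barometric_pressure - 47)
  vals <- vals / filter_gain
  if (inherits(et, "end_tidal_series")) {
    et$et <- vals
    et
  } else vals
}

#' Default steady-state averaging windows
#'
#' Epoch means use late-block windows to avoid transition ramps: the last
#' `hc_last` seconds of each hypercapnia block, the last `ho_last` seconds of
#' each hyperoxia block, and the `baseline_before` seconds immediately
#' preceding each stimulus onset (restricted to baseline/recovery blocks).
#'
#' @param baseline_before,hc_last,ho_last window lengths in seconds.
#' @return A named list.
#' @export
window_policy <- function(baseline_before = 60, hc_last = 60, ho_last = 120) {
  list(baseline_before = baseline_before, hc_last = hc_last, ho_last = ho_last)
}

## windows as data.frame(start, end) per epoch class
epoch_windows <- function(par, policy = window_policy()) {
  stim <- par[par$label %in% c("HC", "HO"), , drop = FALSE]
  hc <- stim[stim$label == "HC", , drop = FALSE]
  ho <- stim[stim$label == "HO", , drop = FALSE]
  base <- lapply(stim$start, function(on) {
    lo <- max(0, on - policy$baseline_before)
    ## clip to preceding baseline/recovery blocks only
    prev <- par[par$end <= on + 1e-9 &
                  par$label %in% c("baseline", "recovery"), , drop = FALSE]
    if (nrow(prev) == 0L) return(NULL)
    lo <- max(lo, max(prev$start[prev$end >= on - 1e-9]))
    if (on - lo < 1e-9) NULL else c(lo, on)
  })
  base <- do.call(rbind, base[!vapply(base, is.null, TRUE)])
  list(
    baseline = base,
    hc = cbind(pmax(hc$start, hc$end - policy$hc_last), hc$end),
    ho = cbind(pmax(ho$start, ho$end - policy$ho_last), ho$end)
  )
}

mean_in_windows <- function(ets, win, what) {
  if (is.null(win) || nrow(win) == 0L)
    stop_quo2("empty epoch window: paradigm defines no %s window", what)
  sel <- rep(FALSE, length(ets$breath_times))
  for (i in seq_len(nrow(win)))
    sel <- sel | (ets$breath_times >= win[i, 1L] &
                    ets$breath_times <= win[i, 2L])
  if (!any(sel))
    stop_quo2("empty epoch window: no breaths in the %s window(s)", what)
  mean(ets$et[sel])
}

#' Epoch gas summary
#'
#' Averages corrected end-tidal O2 and CO2 over the steady-state windows of a
#' paradigm. The two repeats of each stimulus are pooled (breath-weighted).
#'
#' @param et_o2,et_co2 [end_tidal_series()] for O2 and CO2 spanning the
#'   paradigm.
#' @param par a [paradigm()].
#' @param policy a [window_policy()].
#' @return An object of class `epoch_gas_summary` with fields `eto2_0`,
#'   `etco2_0`, `eto2_hc`, `etco2_hc`, `eto2_ho`, `etco2_ho` (mmHg) and the
#'   derived deltas `detco2_hc`, `detco2_ho`, `deto2_ho`.
#' @export
summarize_epochs <- function(et_o2, et_co2, par, policy = window_policy()) {
  stopifnot(inherits(et_o2, "end_tidal_series"),
            inherits(et_co2, "end_tidal_series"),
            inherits(par, "paradigm"))
  if (et_o2$gas != "O2" || et_co2$gas != "CO2")
    stop_quo2("summarize_epochs: series passed in the wrong order")
  w <- epoch_windows(par, policy)
  out <- list(
    eto2_0  = mean_in_windows(et_o2, w$baseline, "baseline"),
    etco2_0 = mean_in_windows(et_co2, w$baseline, "baseline"),
    eto2_hc  = mean_in_windows(et_o2, w$hc, "hypercapnia"),
    etco2_hc = mean_in_windows(et_co2, w$hc, "hypercapnia"),
    eto2_ho  = mean_in_windows(et_o2, w$ho, "hyperoxia"),
    etco2_ho = mean_in_windows(et_co2, w$ho, "hyperoxia")
  )
  out$detco2_hc <- out$etco2_hc - out$etco2_0
  out$detco2_ho <- out$etco2_ho - out$etco2_0
  out$deto2_ho <- out$eto2_ho - out$eto2_0
  if (out$deto2_ho <= 0)
    warning("summarize_epochs: ETO2 did not rise during hyperoxia blocks",
            call. = FALSE)
  structure(out, class = "epoch_gas_summary")
}

#' @export
print.epoch_gas_summary <- function(x, ...) {
  cat("Epoch gas summary (mmHg)\n")
  cat(sprintf("  ETO2  baseline %6.1f  HC %6.1f  HO %6.1f (delta %+.1f)\n",
              x$eto2_0, x$eto2_hc, x$eto2_ho, x$deto2_ho))
  cat(sprintf("  ETCO2 baseline %6.1f  HC %6.1f (delta %+.1f)  HO %6.1f (delta %+.1f)\n",
              x$etco2_0, x$etco2_hc, x$detco2_hc, x$etco2_ho, x$detco2_ho))
  invisible(x)
}

#' Build an epoch gas summary from known values
#'
#' Convenience constructor used when epoch means are already available, e.g.
#' from a published group table or a protocol definition.
#'
#' @param eto2_0,etco2_0,eto2_hc,etco2_hc,eto2_ho,etco2_ho epoch means, mmHg.
#' @return An `epoch_gas_summary`.
#' @export
epoch_gas_summary <- function(eto2_0, etco2_0, eto2_hc = eto2_0,
                              etco2_hc, eto2_ho, etco2_ho = etco2_0) {
  for (v in c(eto2_0, etco2_0, eto2_hc, etco2_hc, eto2_ho, etco2_ho))
    check_number(v, "epoch value", lower = 1e-9)
  out <- list(eto2_0 = eto2_0, etco2_0 = etco2_0, eto2_hc = eto2_hc,
              etco2_hc = etco2_hc, eto2_ho = eto2_ho, etco2_ho = etco2_ho)
  out$detco2_hc <- etco2_hc - etco2_0
  out$detco2_ho <- etco2_ho - etco2_0
  out$deto2_ho <- eto2_ho - eto2_0
  structure(out, class = "epoch_gas_summary")
}

#' Pool per-test means into a protocol mean
#'
#' Plain (optionally weighted) average of repeated-test group means, as used
#' to pool Test A and Test B values into one protocol-level value.
#'
#' @param x numeric vector of per-test means.
#' @param w optional weights (e.g. subject counts).
#' @return The pooled mean.
#' @export
pool_tests <- function(x, w = NULL) {
  check_number(x, "x", allow_vec = TRUE)
  if (is.null(w)) mean(x) else stats::weighted.mean(x, w)
}
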