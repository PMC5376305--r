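#' Solve the calibration model voxelwise
#'
#' Runs the generalized-calibration-model intersection at every parenchymal
#' voxel of a [response_set()], using each voxel's hypercapnia BOLD/CBF inputs,
#' its hyperoxia BOLD change and the single GM-derived uniform hyperoxia CBF
#' ratio `f_ho_global`. Arterial O2 contents come from the epoch gas summary
#' (the hypercapnia epoch uses its own measured ETO2, so hyperventilation
#' drift is handled identically for both curves). Voxels without a valid
#' intersection carry a reason code and are excluded from downstream ROI
#' averaging.
#'
#' @param responses a [response_set()].
#' @param gas an [epoch_gas_summary()].
#' @param bold a [bold_model()].
#' @param blood a [blood_model()].
#' @param k_umol_per_ml ml-to-micromol O2 conversion (44.6 at STP).
#' @param grid_n,tol root-search settings, as in [gcm_fit()].
#' @return An object of class `quo2_maps`: 3D arrays `m`, `oef`, `cmro2`,
#'   logical `solved`, character-coded `status`, plus a `meta` list recording
#'   every constant used.
#' @export
solve_maps <- function(responses, gas, bold = bold_model(),
                       blood = blood_model(), k_umol_per_ml = 44.6,
                       grid_n = 512, tol = 1e-6) {
  stopifnot(inherits(responses, "response_set"),
            inherits(gas, "epoch_gas_summary"))
  check_number(responses$f_ho_global, "f_ho_global", lower = 1e-9)
  d <- responses$dim
  idx <- which(responses$mask &
                 is.finite(responses$b_hc) & is.finite(responses$b_ho) &
                 is.finite(responses$f_hc))
  if (length(idx) == 0L) stop_quo2("solve_maps: empty parenchyma mask")

  cao2_0 <- arterial_o2_content(gas$eto2_0, blood)
  cao2_hc <- arterial_o2_content(gas$eto2_hc, blood)
  cao2_ho <- arterial_o2_content(gas$eto2_ho, blood)
  cap <- blood$phi * blood$hb / 100

  sol <- gcm_core(responses$b_hc[idx], responses$f_hc[idx], cao2_hc,
                  responses$b_ho[idx], responses$f_ho_global, cao2_ho,
                  cao2_0, bold$alpha, bold$beta, cap,
                  grid_n = grid_n, tol = tol)

  blank <- array(NA_real_, d)
  m <- oef <- cmro2 <- blank
  status <- array(NA_integer_, d)
  ok <- sol$status == GCM_STATUS[["solved"]]
  m[idx] <- ifelse(ok, sol$m, NA_real_)
  oef[idx] <- ifelse(ok, sol$oef, NA_real_)
  status[idx] <- sol$status
  cmro2[idx] <- ifelse(ok,
                       cmro2_from_solution(sol$oef, responses$cbf0[idx],
                                           cao2_0, k_umol_per_ml),
                       NA_real_)
  structure(list(m = m, oef = oef, cmro2 = cmro2,
                 solved = array(!is.na(m), d), status = status,
                 dim = d, gm = responses$gm, mask = responses$mask,
                 meta = list(gas = unclass(gas),
                             f_ho_global = responses$f_ho_global,
                             alpha = bold$alpha, beta = bold$beta,
                             blood = unclass(blood),
                             k_umol_per_ml = k_umol_per_ml,
                             cao2 = c(baseline = cao2_0, hc = cao2_hc,
                                      ho = cao2_ho),
                             grid_n = grid_n, tol = tol)),
            class = "quo2_maps")
}

#' @export
print.quo2_maps <- function(x, ...) {
  n_in <- sum(!is.na(x$status))
  n_ok <- sum(x$solved)
  cat(sprintf("Calibration maps: %s grid, %d/%d voxels solved (%.1f%%)\n",
              paste(x$dim, collapse = "x"), n_ok, n_in, 100 * n_ok / n_in))
  if (n_ok) {
    gmsel <- x$solved & x$gm >= 0.5
    if (any(gmsel))
      cat(sprintf("  GM medians: M %.3f, OEF %.3f, CMRO2 %.0f umol/100g/min\n",
                  stats::median(x$m[gmsel]), stats::median(x$oef[gmsel]),
                  stats::median(x$cmro2[gmsel])))
  }
  invisible(x)
}

#' @export
summary.quo2_maps <- function(object, ...) {
  codes <- table(factor(status_label(object$status),
                        levels = names(GCM_STATUS)))
  gmsel <- object$solved & object$gm >= 0.5
  stats_of <- function(v) {
    v <- v[gmsel]
    c(median = stats::median(v), iqr = stats::IQR(v))
  }
  out <- list(status_counts = codes,
              gm = if (any(gmsel))
                rbind(M = stats_of(object$m), OEF = stats_of(object$oef),
                      CMRO2 = stats_of(object$cmro2)) else NULL,
              meta = object$meta)
  class(out) <- "summary.quo2_maps"
  out
}

#' @export
print.summary.quo2_maps <- function(x, ...) {
  cat("Voxelwise GCM solution summary\n  status counts:\n")
  print(x$status_counts)
  if (!is.null(x$gm)) {
    cat("  GM (probability >= 0.5), solved voxels:\n")
    print(round(x$gm, 3))
  }
  invisible(x)
}

#' Write calibration maps to NIfTI
#'
#' Writes `m.nii.gz`, `oef.nii.gz`, `cmro2.nii.gz` and `status.nii.gz`
#' alongside a JSON provenance sidecar with every constant used in the solve.
#'
#' @param maps a `quo2_maps` object from [solve_maps()].
#' @param dir output directory (created if needed).
#' @param template optional NIfTI image or header to inherit geometry from.
#' @return Invisibly, the paths written.
#' @export
write_maps <- function(maps, dir, template = NULL) {
  stopifnot(inherits(maps, "quo2_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("m", "oef", "cmro2", "status")) {
    img <- maps[[nm]]
    if (nm == "status") img[is.na(img)] <- -1L
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img, reference = template), p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, "provenance.json")
  jsonlite::write_json(
    list(package = "quo2calib",
         version = as.character(utils::packageVersion("quo2calib")),
         constants = maps$meta,
         status_codes = as.list(GCM_STATUS)),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, side))
}
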