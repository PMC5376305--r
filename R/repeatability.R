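#' ROI definition with GM-probability weights
#'
#' Voxelwise weights are the product of GM probability and ROI membership,
#' zeroed where GM probability is below 0.5 and (downstream) at voxels the
#' calibration model could not solve.
#'
#' @param name ROI label.
#' @param weights 3D array of weights in [0, 1] with at least one positive
#'   entry.
#' @return An object of class `roi_definition`.
#' @export
roi_definition <- function(name, weights) {
  if (any(!is.finite(weights) | weights < 0 | weights > 1))
    stop_quo2("roi_definition: weights must be finite, in [0, 1]")
  if (!any(weights > 0))
    stop_quo2("roi_definition: at least one positive weight required")
  structure(list(name = name, weights = weights), class = "roi_definition")
}

#' Build an ROI from a membership mask and GM probability
#'
#' @param name ROI label.
#' @param membership 3D membership array (0/1 or probability).
#' @param gm 3D GM-probability array; voxels below `gm_min` are zeroed.
#' @param solved optional logical array; unsolved voxels are zeroed.
#' @param gm_min GM-probability threshold (default 0.5).
#' @return A [roi_definition()].
#' @export
roi_from_masks <- function(name, membership, gm, solved = NULL,
                           gm_min = 0.5) {
  w <- membership * gm
  w[gm < gm_min] <- 0
  if (!is.null(solved)) w[!solved] <- 0
  roi_definition(name, w)
}

#' Weighted ROI mean of a map
#'
#' sum(w v) / sum(w) over voxels with finite map values and positive weight.
#'
#' @param map 3D array.
#' @param roi a [roi_definition()] (or a bare weight array).
#' @return Scalar weighted mean.
#' @export
roi_mean <- function(map, roi) {
  w <- if (inherits(roi, "roi_definition")) roi$weights else roi
  if (length(w) != length(map))
    stop_quo2("roi_mean: map and ROI geometry differ")
  sel <- is.finite(map) & w > 0
  if (!any(sel)) stop_quo2("empty ROI: no finite voxels with positive weight")
  sum(w[sel] * map[sel]) / sum(w[sel])
}

#' Decide the analysis scale for repeatability statistics
#'
#' Screens the per-subject test differences for (a) non-normality
#' (Shapiro-Wilk) and (b) proportionality of the error magnitude to the
#' measurement mean (Kendall rank correlation of |difference| vs subject
#' mean). If either screen rejects at `alpha`, the data are re-screened on the
#' log10 scale; if the log scale passes, repeatability is assessed there,
#' otherwise on the original values.
#'
#' @param diffs per-subject test differences (test A - test B), length >= 3.
#' @param means per-subject means of the two tests.
#' @param alpha screening significance level.
#' @return A list: `scale` (`"original"` or `"log10"`), the screening
#'   p-values on both scales, and a `note` for degenerate inputs.
#' @export
scale_decision <- function(diffs, means, alpha = 0.05) {
  if (length(diffs) != length(means) || length(diffs) < 3L)
    stop_quo2("scale_decision: need >= 3 paired differences")
  out <- list(scale = "original", shapiro_p = NA_real_, kendall_p = NA_real_,
              log_shapiro_p = NA_real_, log_kendall_p = NA_real_, note = NULL)
  if (stats::sd(diffs) == 0) {
    out$note <- "degenerate: all differences equal; original scale kept"
    return(out)
  }
  screen <- function(d, m) {
    sp <- stats::shapiro.test(d)$p.value
    kp <- if (stats::sd(abs(d)) == 0 || stats::sd(m) == 0) 1
    else suppressWarnings(
      stats::cor.test(abs(d), m, method = "kendall")$p.value)
    c(shapiro = sp, kendall = kp)
  }
  p <- screen(diffs, means)
  out$shapiro_p <- p[["shapiro"]]; out$kendall_p <- p[["kendall"]]
  if (all(p >= alpha)) return(out)
  a <- means + diffs / 2
  b <- means - diffs / 2
  if (any(a <= 0 | b <= 0)) {
    out$note <- "non-positive values: log10 scale unavailable"
    return(out)
  }
  lp <- screen(log10(a) - log10(b), (log10(a) + log10(b)) / 2)
  out$log_shapiro_p <- lp[["shapiro"]]; out$log_kendall_p <- lp[["kendall"]]
  if (all(lp >= alpha)) out$scale <- "log10"
  else out$note <- "both scales failed screening; original scale kept"
  out
}

#' Within-subject repeatability statistics
#'
#' With two measurements per subject: dSD is the (n-1) standard deviation of
#' the per-subject differences, wsSD = dSD / sqrt(2), and
#' wsCV = 100 sqrt(mean_i (wsSD / mean_i)^2) on the original scale, where
#' mean_i is subject i's mean of the two tests. On the log10 scale
#' wsCV = 100 (10^wsSD - 1).
#'
#' @param a,b per-subject values for test A and test B (equal length >= 2).
#' @param scale `"original"` or `"log10"` (see [scale_decision()]).
#' @return A list with `dsd`, `wssd`, `wscv` (percent) and `scale`.
#' @export
within_subject_stats <- function(a, b, scale = c("original", "log10")) {
  scale <- match.arg(scale)
  if (length(a) != length(b) || length(a) < 2L)
    stop_quo2("within_subject_stats: need equal-length vectors, n >= 2")
  if (scale == "log10") {
    if (any(a <= 0 | b <= 0))
      stop_quo2("within_subject_stats: log10 scale needs positive values")
    la <- log10(a); lb <- log10(b)
    dsd <- stats::sd(la - lb)
    wssd <- dsd / sqrt(2)
    wscv <- 100 * (10^wssd - 1)
  } else {
    dsd <- stats::sd(a - b)
    wssd <- dsd / sqrt(2)
    subj_mean <- (a + b) / 2
    if (any(subj_mean == 0))
      stop_quo2("within_subject_stats: subject mean of zero; wsCV undefined")
    wscv <- 100 * sqrt(mean((wssd / subj_mean)^2))
  }
  list(dsd = dsd, wssd = wssd, wscv = wscv, scale = scale)
}

#' Between-subject coefficient of variation
#'
#' 100 SD / mean of the pooled values from both tests ((n-1) denominator).
#'
#' @param pooled all values from both tests, length >= 2.
#' @return bsCV in percent.
#' @export
between_subject_cv <- function(pooled) {
  if (length(pooled) < 2L)
    stop_quo2("between_subject_cv: need >= 2 values")
  m <- mean(pooled)
  if (m == 0) stop_quo2("between_subject_cv: mean of zero; CV undefined")
  100 * stats::sd(pooled) / m
}

#' Pairwise ROI comparison with family-wise error control
#'
#' Two-tailed paired t-tests between all ROI pairs on subject-matched pooled
#' values, Holm-Bonferroni corrected at family-wise level `alpha`.
#'
#' @param values numeric matrix, subjects (rows) x ROIs (columns), complete
#'   cases only; column names label the ROIs.
#' @param alpha family-wise error level.
#' @return A list with symmetric matrices `p_raw`, `p_adj` and logical
#'   `significant`.
#' @export
compare_rois <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop_quo2("compare_rois: need >= 2 ROIs")
  if (any(!is.finite(values)))
    stop_quo2("compare_rois: unequal subject counts per ROI (missing values)")
  k <- ncol(values)
  nm <- colnames(values) %||% paste0("roi", seq_len(k))
  pairs <- utils::combn(k, 2)
  p <- apply(pairs, 2L, function(ij)
    stats::t.test(values[, ij[1L]], values[, ij[2L]], paired = TRUE)$p.value)
  padj <- stats::p.adjust(p, method = "holm")
  mk <- function(v, init) {
    m <- matrix(init, k, k, dimnames = list(nm, nm))
    for (c_i in seq_len(ncol(pairs))) {
      i <- pairs[1L, c_i]; j <- pairs[2L, c_i]
      m[i, j] <- m[j, i] <- v[c_i]
    }
    m
  }
  list(p_raw = mk(p, NA_real_), p_adj = mk(padj, NA_real_),
       significant = mk(padj < alpha, FALSE))
}

#' Full repeatability report over ROIs and test combinations
#'
#' Takes tidy long-format data (`subject`, `protocol` in LHO/HHO, `test` in
#' A/B, `roi`, `estimate`, `value`) and computes, for each estimate and ROI,
#' the three canonical test combinations: A vs B within LHO, A vs B within
#' HHO, and test A LHO vs test A HHO. Each combination gets a scale decision,
#' dSD/wsSD/wsCV, the between-subject CV of the pooled values, and a paired
#' t-test between the two arms.
#'
#' @param data data frame with the columns named above.
#' @param alpha screening/test significance level.
#' @return A data frame with one row per (estimate, roi, combination).
#' @export
repeatability_report <- function(data, alpha = 0.05) {
  need <- c("subject", "protocol", "test", "roi", "estimate", "value")
  if (!all(need %in% names(data)))
    stop_quo2("repeatability_report: data needs columns %s",
              paste(need, collapse = ", "))
  combos <- list(
    AB_LHO = list(a = c("LHO", "A"), b = c("LHO", "B")),
    AB_HHO = list(a = c("HHO", "A"), b = c("HHO", "B")),
    A_LHO_vs_HHO = list(a = c("LHO", "A"), b = c("HHO", "A"))
  )
  grab <- function(d, arm, subj) {
    sel <- d$protocol == arm[1L] & d$test == arm[2L]
    v <- d$value[sel][match(subj, d$subject[sel])]
    v
  }
  rows <- list()
  for (est in unique(data$estimate)) for (roi in unique(data$roi)) {
    d <- data[data$estimate == est & data$roi == roi, , drop = FALSE]
    for (cmb in names(combos)) {
      arms <- combos[[cmb]]
      subj <- sort(unique(d$subject))
      a <- grab(d, arms$a, subj); b <- grab(d, arms$b, subj)
      keep <- is.finite(a) & is.finite(b)
      if (sum(keep) < 3L) next
      a <- a[keep]; b <- b[keep]
      dec <- scale_decision(a - b, (a + b) / 2, alpha)
      ws <- within_subject_stats(a, b, dec$scale)
      rows[[length(rows) + 1L]] <- data.frame(
        estimate = est, roi = roi, combination = cmb, n = length(a),
        scale = dec$scale, shapiro_p = dec$shapiro_p,
        kendall_p = dec$kendall_p, dsd = ws$dsd, wssd = ws$wssd,
        wscv = ws$wscv, bscv = between_subject_cv(c(a, b)),
        paired_t_p = stats::t.test(a, b, paired = TRUE)$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop_quo2("repeatability_report: no combination had >= 3 complete pairs")
  do.call(rbind, rows)
}
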