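#' Peak metrics of a single-peak chromatogram
#'
#' Extracts the elution-peak apex, height, full width at half maximum and the
#' on-column dilution factor from a single-peak SEC trace. A baseline (the
#' median of the first and last 5% of samples) is subtracted first. The apex
#' is refined by a parabola through the three samples around the maximum; the
#' FWHM comes from linear interpolation of the half-maximum crossings. The
#' dilution factor is FWHM divided by the injection volume, the standard
#' band-broadening estimate used to convert loaded to on-column
#' concentration.
#'
#' @param chrom A [chromatogram()].
#' @param smooth_window Adjacent-averaging window applied to the signal
#'   before peak extraction (see [smooth_adjacent_average()]); 1 disables
#'   smoothing. Noisy traces benefit from a modest window (the Kd pipeline
#'   uses 9 by default).
#' @param baseline_frac Fraction of samples at each end used for the baseline
#'   estimate.
#' @return An object of class `"peak_metrics"`: `apex_volume_ml`,
#'   `apex_height`, `fwhm_ml`, `dilution_factor`.
#'   Errors: `"truncated peak"` when the maximum sits at a trace end or the
#'   half-max region is cut off; `"multi-peak trace"` when more than one
#'   region rises above half maximum.
#' @examples
#' v <- seq(6, 12, 0.01)
#' ch <- chromatogram(v, exp(-(v - 10)^2 / (2 * 0.34^2)), load_volume_ml = 0.1)
#' peak_metrics(ch)
#' @export
peak_metrics <- function(chrom, smooth_window = 1L, baseline_frac = 0.05) {
  stopifnot(inherits(chrom, "chromatogram"))
  v <- chrom$volume_ml
  s <- chrom$signal
  n <- length(s)
  n_edge <- max(1L, floor(baseline_frac * n))
  base <- stats::median(c(s[seq_len(n_edge)], s[seq.int(n - n_edge + 1L, n)]))
  s <- s - base
  if (smooth_window > 1) s <- smooth_adjacent_average(s, smooth_window)
  imax <- which(s == max(s))
  if (length(imax) > 1) {
    warning("tied maxima; using leftmost")
    imax <- imax[1]
  }
  if (imax == 1L || imax == n) stop("truncated peak: maximum at trace end")
  # parabolic apex through the three samples around the maximum
  x3 <- v[(imax - 1L):(imax + 1L)]; y3 <- s[(imax - 1L):(imax + 1L)]
  qf <- stats::lm.fit(cbind(1, x3, x3^2), y3)$coefficients
  if (is.na(qf[3]) || qf[3] >= 0) {
    apex_v <- v[imax]; apex_h <- s[imax]
  } else {
    apex_v <- -qf[2] / (2 * qf[3])
    apex_h <- qf[1] + qf[2] * apex_v + qf[3] * apex_v^2
  }
  half <- apex_h / 2
  above <- s > half
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  up <- which(runs$values)
  # ignore sub-3-sample noise blips above the half line
  substantive <- up[runs$lengths[up] >= 3L | (starts[up] <= imax & ends[up] >= imax)]
  apex_run <- substantive[starts[substantive] <= imax & ends[substantive] >= imax]
  if (length(apex_run) != 1L) stop("truncated peak: apex not above half maximum")
  if (length(substantive) > 1L) stop("multi-peak trace: multiple regions above half maximum")
  i_lo <- starts[apex_run]; i_hi <- ends[apex_run]
  if (i_lo == 1L || i_hi == n) stop("truncated peak: half-maximum region reaches trace end")
  interp_cross <- function(i0, i1) {
    v[i0] + (half - s[i0]) * (v[i1] - v[i0]) / (s[i1] - s[i0])
  }
  left <- interp_cross(i_lo - 1L, i_lo)
  right <- interp_cross(i_hi, i_hi + 1L)
  fwhm <- right - left
  structure(list(apex_volume_ml = unname(apex_v),
                 apex_height = unname(apex_h),
                 fwhm_ml = unname(fwhm),
                 dilution_factor = unname(fwhm / chrom$load_volume_ml)),
            class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf(
    "Peak: apex %.3f mL (height %.4g), FWHM %.3f mL, dilution factor %.2f\n",
    x$apex_volume_ml, x$apex_height, x$fwhm_ml, x$dilution_factor))
  invisible(x)
}

# coefficient of determination, stable for exact fits (summary.lm warns)
r_squared <- function(fit) {
  y <- fit$model[[1]]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum(stats::resid(fit)^2) / tss))
}

#' Fit a size-exclusion column calibration
#'
#' Ordinary least squares of log10 molecular mass on elution volume for a set
#' of protein standards, the conventional SEC calibration line. Larger
#' proteins elute earlier, so a physically sensible calibration has negative
#' slope; a non-negative slope triggers a warning.
#'
#' @param standards Data frame with columns `mw_kda` and `ve_ml` (and
#'   optionally `name`); at least 3 standards with distinct elution volumes.
#' @return An object of class `"sec_calibration"` with `slope`
#'   (d log10 MW / d mL), `intercept` (log10 kDa), `r_squared` and the
#'   standards table.
#' @examples
#' std <- data.frame(mw_kda = c(66, 43, 29, 17.6, 12.4))
#' std$ve_ml <- (3 - log10(std$mw_kda)) / 0.2
#' cal <- fit_sec_calibration(std)
#' apparent_mw(cal, 8.719)
#' @export
fit_sec_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("mw_kda", "ve_ml") %in% names(standards))) {
    stop("standards must have columns mw_kda and ve_ml")
  }
  if (nrow(standards) < 3) stop("need at least 3 calibration standards")
  if (anyDuplicated(standards$ve_ml)) stop("standards must have distinct ve_ml")
  fit <- stats::lm(log10(mw_kda) ~ ve_ml, data = standards)
  cf <- stats::coef(fit)
  if (cf[2] >= 0) warning("non-physical calibration: slope >= 0")
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r_squared(fit),
                 standards = standards),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "SEC calibration: log10 MW(kDa) = %.4f %+.4f * Ve(mL)  (R^2 = %.4f, %d standards)\n",
    x$intercept, x$slope, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' @export
coef.sec_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Apparent molecular mass from a calibration
#'
#' Inverts the calibration line: MW = 10^(intercept + slope * Ve). Warns when
#' the queried volume falls outside the calibrated range extended by 10% of
#' its span.
#'
#' @param cal A [fit_sec_calibration()] object.
#' @param ve_ml Elution volume(s) in mL.
#' @return Apparent molecular mass(es) in kDa.
#' @export
apparent_mw <- function(cal, ve_ml) {
  stopifnot(inherits(cal, "sec_calibration"))
  rng <- range(cal$standards$ve_ml)
  pad <- 0.1 * diff(rng)
  if (any(ve_ml < rng[1] - pad | ve_ml > rng[2] + pad)) {
    warning("elution volume outside calibration range; extrapolating")
  }
  10^(cal$intercept + cal$slope * ve_ml)
}

#' @export
predict.sec_calibration <- function(object, ve_ml, ...) {
  apparent_mw(object, ve_ml)
}
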