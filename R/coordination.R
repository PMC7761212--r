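#' Pair of coordination reference spectra
#'
#' Holds the two endmember deoxy spectra used to quantify heme
#' hexacoordination: a pure hexacoordinate reference (distal histidine bound,
#' resolved alpha/beta bands, as in deoxy class-2 hemoglobin) and a pure
#' pentacoordinate reference (distal-histidine mutant, one broad band). Both
#' must cover 450-650 nm and be strictly positive over the 530-570 nm band
#' region. The chosen normalization makes the two endmembers commensurate
#' before mixing or unmixing.
#'
#' @param hexa,penta [spectrum()] objects.
#' @param normalization `"area"` (unit trapezoidal area over 450-650 nm,
#'   default), `"wavelength"` (unit value at `norm_wavelength`), or
#'   `"none"`.
#' @param norm_wavelength Wavelength (nm) for `"wavelength"` normalization.
#' @return An object of class `"reference_pair"`.
#' @export
reference_pair <- function(hexa, penta,
                           normalization = c("area", "wavelength", "none"),
                           norm_wavelength = 555) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(hexa, "spectrum"), inherits(penta, "spectrum"))
  for (s in list(hexa = hexa, penta = penta)) {
    if (min(s$wavelength_nm) > 450 || max(s$wavelength_nm) < 650) {
      stop("reference spectra must cover [450, 650] nm")
    }
    band <- s$value[s$wavelength_nm >= 530 & s$wavelength_nm <= 570]
    if (any(band <= 0)) {
      stop("reference spectra must be strictly positive on [530, 570] nm")
    }
  }
  norm1 <- function(s) {
    z <- switch(normalization,
      area = trapz(s$wavelength_nm, s$value,
                   lo = 450, hi = 650),
      wavelength = spec_value_at(s, norm_wavelength),
      none = 1)
    if (!is.finite(z) || z <= 0) stop("degenerate normalization constant")
    spectrum(s$wavelength_nm, s$value / z, meta = s$meta)
  }
  structure(list(hexa = norm1(hexa), penta = norm1(penta),
                 normalization = normalization),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf(
    "Reference pair (%s-normalized): hexa A555/A540 = %.3f, penta = %.3f\n",
    x$normalization, band_ratio(x$hexa), band_ratio(x$penta)))
  invisible(x)
}

# trapezoidal integral of a sampled trace, restricted to [lo, hi]
trapz <- function(x, y, lo = -Inf, hi = Inf) {
  keep <- x >= lo & x <= hi
  x <- x[keep]; y <- y[keep]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# linearly interpolated spectrum value at a single wavelength
spec_value_at <- function(spec, wl) {
  if (wl < min(spec$wavelength_nm) || wl > max(spec$wavelength_nm)) {
    stop("wavelength ", wl, " nm outside spectrum range")
  }
  stats::approx(spec$wavelength_nm, spec$value, xout = wl)$y
}

#' Absorbance band ratio
#'
#' Ratio of the spectrum values at two wavelengths (default A555/A540, the
#' standard indicator of deoxy heme hexacoordination: the hexacoordinate
#' alpha/beta band structure raises A540 relative to the broad
#' pentacoordinate band). Values are linearly interpolated between samples.
#'
#' @param spec A [spectrum()].
#' @param num_nm,den_nm Numerator and denominator wavelengths (nm).
#' @return The ratio (numeric scalar).
#' @export
band_ratio <- function(spec, num_nm = 555, den_nm = 540) {
  stopifnot(inherits(spec, "spectrum"))
  num <- spec_value_at(spec, num_nm)
  den <- spec_value_at(spec, den_nm)
  if (den <= 0) stop("denominator absorbance <= 0")
  num / den
}

#' Pentacoordinate fraction from a band ratio
#'
#' Inverts the two-endmember mixture for the observed A555/A540 ratio. The
#' ratio of a mixture is a rational (not linear) function of the fraction f,
#' so the inversion uses the references' absolute (post-normalization) values
#' at both wavelengths:
#' \deqn{f = (H_{555} - r H_{540}) /
#'   [(r P_{540} - P_{555}) - (r H_{540} - H_{555})].}
#' Solutions outside `[0, 1]` are clipped with a warning.
#'
#' @param r_obs Observed A555/A540 ratio (see [band_ratio()]).
#' @param refs A [reference_pair()].
#' @return An object of class `"coordination_estimate"` with `f_penta`,
#'   `method = "ratio"` and `ratio_observed`.
#' @export
penta_fraction_from_ratio <- function(r_obs, refs) {
  stopifnot(inherits(refs, "reference_pair"))
  h555 <- spec_value_at(refs$hexa, 555); h540 <- spec_value_at(refs$hexa, 540)
  p555 <- spec_value_at(refs$penta, 555); p540 <- spec_value_at(refs$penta, 540)
  if (abs(h555 / h540 - p555 / p540) <= 1e-6) {
    stop("references indistinguishable: band ratios equal")
  }
  f <- (h555 - r_obs * h540) /
    ((r_obs * p540 - p555) - (r_obs * h540 - h555))
  if (f < -1e-9 || f > 1 + 1e-9) {
    warning("ratio solution outside [0, 1]; clipped")
  }
  f <- min(max(f, 0), 1)
  structure(list(f_penta = f, method = "ratio", ratio_observed = r_obs,
                 residual = NA_real_),
            class = "coordination_estimate")
}

#' Pentacoordinate fraction by full-band unmixing
#'
#' Least-squares decomposition of a deoxy spectrum into the two reference
#' endmembers over a wavelength window:
#' \deqn{A(\lambda) \approx c\,[f P(\lambda) + (1-f) H(\lambda)],\quad
#'   c > 0,\ f \in [0, 1],}
#' where the free scale c absorbs concentration and pathlength, making the
#' estimate invariant to rescaling the input. Solved as nonnegative least
#' squares in the two component amplitudes (a = c f, b = c (1-f)); a
#' negative unconstrained amplitude is clamped to the corresponding boundary
#' (f = 0 or f = 1).
#'
#' @param spec A [spectrum()] covering the window.
#' @param refs A [reference_pair()].
#' @param window_nm Length-2 numeric window in nm (default `c(500, 600)`),
#'   at least 20 nm wide.
#' @return A `"coordination_estimate"` with `f_penta`, `method = "unmix"`
#'   and `residual` (residual L2 norm over the window).
#' @export
penta_fraction_unmix <- function(spec, refs, window_nm = c(500, 600)) {
  stopifnot(inherits(spec, "spectrum"), inherits(refs, "reference_pair"))
  if (diff(window_nm) < 20) stop("unmixing window narrower than 20 nm")
  wl <- spec$wavelength_nm
  keep <- wl >= window_nm[1] & wl <= window_nm[2]
  if (min(wl) > window_nm[1] || max(wl) < window_nm[2] ||
      sum(keep) < 3 ||
      min(refs$hexa$wavelength_nm) > window_nm[1] ||
      max(refs$hexa$wavelength_nm) < window_nm[2] ||
      min(refs$penta$wavelength_nm) > window_nm[1] ||
      max(refs$penta$wavelength_nm) < window_nm[2]) {
    stop("spectrum and references must cover the unmixing window")
  }
  wl <- wl[keep]
  y <- spec$value[keep]
  P <- stats::approx(refs$penta$wavelength_nm, refs$penta$value, xout = wl)$y
  H <- stats::approx(refs$hexa$wavelength_nm, refs$hexa$value, xout = wl)$y
  X <- cbind(P, H)
  ab <- stats::lm.fit(X, y)$coefficients
  if (any(!is.finite(ab))) stop("degenerate unmixing system")
  clipped <- FALSE
  tol <- 1e-8 * max(abs(ab))  # rounding-level negatives are not violations
  ab[ab < 0 & ab > -tol] <- 0
  if (ab[1] < 0 || ab[2] < 0) {
    # boundary solutions: pure hexa (f = 0) or pure penta (f = 1)
    cH <- sum(H * y) / sum(H * H)
    cP <- sum(P * y) / sum(P * P)
    rssH <- sum((y - cH * H)^2)
    rssP <- sum((y - cP * P)^2)
    ab <- if (rssH <= rssP) c(0, max(cH, 0)) else c(max(cP, 0), 0)
    clipped <- TRUE
  }
  f <- ab[1] / (ab[1] + ab[2])
  if (clipped) warning("unconstrained amplitude negative; f clipped to [0, 1]")
  resid <- sqrt(sum((y - X %*% ab)^2))
  structure(list(f_penta = unname(f), method = "unmix",
                 ratio_observed = NA_real_, residual = resid),
            class = "coordination_estimate")
}

#' @export
print.coordination_estimate <- function(x, ...) {
  cat(sprintf("Pentacoordinate fraction (%s): f = %.3f (%.1f%%)\n",
              x$method, x$f_penta, 100 * x$f_penta))
  invisible(x)
}

#' Pentacoordinate fraction across a concentration series
#'
#' Applies one of the two estimators to each spectrum of a concentration
#' series and tabulates f against concentration (sorted ascending). Errors
#' on individual spectra are recorded in the `error` column and the series
#' continues.
#'
#' @param spectra Named or unnamed list of [spectrum()] objects, or a list
#'   of `list(conc_uM =, spectrum =)` pairs; concentrations are taken from
#'   `conc_uM`, from each spectrum's `meta$conc_uM`, or from names.
#' @param refs A [reference_pair()].
#' @param method `"unmix"` (default) or `"ratio"`.
#' @return Data frame with columns `conc_uM`, `f_penta`, `error`.
#' @export
coordination_series <- function(spectra, refs,
                                method = c("unmix", "ratio")) {
  method <- match.arg(method)
  if (length(spectra) < 2) stop("need at least 2 spectra in a series")
  entries <- lapply(spectra, function(el) {
    if (inherits(el, "spectrum")) {
      conc <- el$meta$conc_uM
      if (is.null(conc)) stop("spectrum lacks meta$conc_uM")
      list(conc_uM = as.numeric(conc), spectrum = el)
    } else {
      list(conc_uM = as.numeric(el$conc_uM), spectrum = el$spectrum)
    }
  })
  rows <- lapply(entries, function(e) {
    est <- tryCatch({
      if (method == "unmix") penta_fraction_unmix(e$spectrum, refs)
      else penta_fraction_from_ratio(band_ratio(e$spectrum), refs)
    }, error = function(err) err)
    if (inherits(est, "error")) {
      data.frame(conc_uM = e$conc_uM, f_penta = NA_real_,
                 error = conditionMessage(est))
    } else {
      data.frame(conc_uM = e$conc_uM, f_penta = est$f_penta,
                 error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$conc_uM), , drop = FALSE]
}
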