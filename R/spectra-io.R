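#' Construct a spectrum object
#'
#' A spectrum is a wavelength/value trace (absorbance in AU or ellipticity in
#' mdeg) with free-form metadata such as species, redox state, concentration
#' and cuvette pathlength.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm. Must be strictly
#'   increasing after sorting; duplicated wavelengths are an error.
#' @param value Numeric vector of the same length (>= 2).
#' @param meta Named list of metadata. If `pathlength_cm` is present it must
#'   be a positive number.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength_nm`, `value` and `meta`.
#' @examples
#' s <- spectrum(seq(450, 650, 1), exp(-((seq(450, 650, 1) - 555) / 10)^2))
#' band_ratio(s)
#' @export
spectrum <- function(wavelength_nm, value, meta = list()) {
  xy <- validate_xy(wavelength_nm, value, xname = "wavelength_nm")
  if (!is.null(meta$pathlength_cm)) {
    plc <- as.numeric(meta$pathlength_cm)
    if (!is.finite(plc) || plc <= 0) stop("pathlength_cm must be > 0")
  }
  structure(list(wavelength_nm = xy$x, value = xy$y, meta = meta),
            class = "spectrum")
}

#' Construct a chromatogram object
#'
#' A size-exclusion elution trace (signal vs elution volume) together with the
#' injection ("load") volume and the loaded protein concentration, both needed
#' for the on-column dilution correction.
#'
#' @param volume_ml Numeric vector of elution volumes in mL, strictly
#'   increasing (sorted with a warning if supplied out of order).
#' @param signal Numeric detector signal, same length.
#' @param load_volume_ml Injection volume in mL (> 0). Defaults to 0.1 mL, the
#'   conventional 100 uL analytical injection.
#' @param loaded_conc_uM Loaded protein concentration in uM, expressed in
#'   dimer equivalents (`NA` if unknown).
#' @param meta Named list of metadata.
#' @return An object of class `"chromatogram"`.
#' @export
chromatogram <- function(volume_ml, signal, load_volume_ml = 0.1,
                         loaded_conc_uM = NA_real_, meta = list()) {
  xy <- validate_xy(volume_ml, signal, xname = "volume_ml")
  if (!is.finite(load_volume_ml) || load_volume_ml <= 0) {
    stop("load_volume_ml must be > 0")
  }
  if (!is.na(loaded_conc_uM) &&
      (!is.finite(loaded_conc_uM) || loaded_conc_uM < 0)) {
    stop("loaded_conc_uM must be >= 0")
  }
  structure(list(volume_ml = xy$x, signal = xy$y,
                 load_volume_ml = load_volume_ml,
                 loaded_conc_uM = loaded_conc_uM, meta = meta),
            class = "chromatogram")
}

#' Construct a melt-curve object
#'
#' A thermal unfolding trace: CD signal (typically mdeg at 222 nm) against
#' temperature.
#'
#' @param temperature_c Strictly increasing temperatures in degrees C,
#'   length >= 8.
#' @param signal Numeric signal of the same length.
#' @param meta Named list of metadata.
#' @return An object of class `"melt_curve"`.
#' @export
melt_curve <- function(temperature_c, signal, meta = list()) {
  xy <- validate_xy(temperature_c, signal, xname = "temperature_c")
  if (length(xy$x) < 8) stop("melt curve needs at least 8 points")
  structure(list(temperature_c = xy$x, signal = xy$y, meta = meta),
            class = "melt_curve")
}

# Shared x/y validation: numeric, equal length >= 2, strictly increasing
# (out-of-order input sorted with a warning, ties are an error).
validate_xy <- function(x, y, xname = "x") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop(xname, " and value must have equal length")
  if (length(x) < 2) stop("insufficient data: need at least 2 points")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  if (is.unsorted(x, strictly = TRUE)) {
    if (anyDuplicated(x)) stop(xname, " contains duplicated values")
    warning(xname, " not sorted; sorting ascending")
    o <- order(x)
    x <- x[o]; y <- y[o]
  }
  list(x = x, y = y)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points, %.1f-%.1f nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "Chromatogram: %d points, %.2f-%.2f mL (load %.3f mL, %.4g uM loaded)\n",
    length(x$volume_ml), min(x$volume_ml), max(x$volume_ml),
    x$load_volume_ml, x$loaded_conc_uM))
  invisible(x)
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("Melt curve: %d points, %.1f-%.1f degC\n",
              length(x$temperature_c), min(x$temperature_c),
              max(x$temperature_c)))
  invisible(x)
}

#' Read a two-column CSV trace
#'
#' Reads the plain-text trace format used throughout the package: optional
#' leading metadata lines of the form `# key: value`, an optional column
#' header, then two numeric comma-separated columns. The metadata keys
#' `load_volume_ml` and `loaded_conc_uM` populate the corresponding
#' chromatogram fields.
#'
#' @param path Path to a CSV file.
#' @param kind One of `"spectrum"` (wavelength_nm,value),
#'   `"chromatogram"` (volume_ml,signal) or `"melt"` (temperature_c,signal).
#' @return A [spectrum()], [chromatogram()] or [melt_curve()] object. Rows
#'   out of order are sorted with a warning; a non-numeric data row is a
#'   parse error naming the offending line.
#' @export
read_xy_csv <- function(path, kind = c("spectrum", "chromatogram", "melt")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  is_meta <- grepl("^#", lines_trim)
  # metadata only honoured as a leading block
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1 else length(lines)
  meta <- list()
  if (n_meta > 0) {
    for (ln in lines_trim[seq_len(n_meta)]) {
      m <- regmatches(ln, regexec("^#\\s*([^:]+?)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(m) == 3) meta[[m[2]]] <- m[3]
    }
  }
  body_idx <- setdiff(seq_along(lines), seq_len(n_meta))
  body_idx <- body_idx[nzchar(lines_trim[body_idx])]
  if (length(body_idx) == 0) stop("insufficient data: no rows in ", path)
  # optional header row: first body line whose fields are not all numeric
  first <- strsplit(lines_trim[body_idx[1]], ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  data_idx <- if (has_header) body_idx[-1] else body_idx
  if (length(data_idx) < 2) stop("insufficient data: fewer than 2 rows")
  parts <- strsplit(lines_trim[data_idx], ",")
  bad_ncol <- lengths(parts) < 2
  if (any(bad_ncol)) {
    stop("parse error at line ", data_idx[which(bad_ncol)[1]],
         ": expected 2 comma-separated columns")
  }
  x <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  bad <- is.na(x) | is.na(y)
  if (any(bad)) {
    stop("parse error at line ", data_idx[which(bad)[1]],
         ": non-numeric value")
  }
  switch(kind,
    spectrum = spectrum(x, y, meta = meta),
    chromatogram = {
      lv <- if (!is.null(meta$load_volume_ml))
        as.numeric(meta$load_volume_ml) else 0.1
      lc <- if (!is.null(meta$loaded_conc_uM))
        as.numeric(meta$loaded_conc_uM) else NA_real_
      chromatogram(x, y, load_volume_ml = lv, loaded_conc_uM = lc,
                   meta = meta)
    },
    melt = melt_curve(x, y, meta = meta))
}

#' Write a two-column CSV trace
#'
#' Inverse of [read_xy_csv()]: writes `# key: value` metadata lines, a
#' header, then the two numeric columns.
#'
#' @param obj A spectrum, chromatogram or melt_curve.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xy_csv <- function(obj, path) {
  if (inherits(obj, "spectrum")) {
    x <- obj$wavelength_nm; y <- obj$value
    hdr <- "wavelength_nm,value"; meta <- obj$meta
  } else if (inherits(obj, "chromatogram")) {
    x <- obj$volume_ml; y <- obj$signal
    hdr <- "volume_ml,signal"
    meta <- obj$meta
    meta$load_volume_ml <- obj$load_volume_ml
    meta$loaded_conc_uM <- obj$loaded_conc_uM
  } else if (inherits(obj, "melt_curve")) {
    x <- obj$temperature_c; y <- obj$signal
    hdr <- "temperature_c,signal"; meta <- obj$meta
  } else stop("unsupported object")
  meta_lines <- if (length(meta)) {
    paste0("# ", names(meta), ": ", vapply(meta, format, ""))
  } else character()
  writeLines(c(meta_lines, hdr,
               paste(format(x, trim = TRUE, digits = 15),
                     format(y, trim = TRUE, digits = 15), sep = ",")),
             path)
  invisible(path)
}

#' Adjacent-averaging smoothing
#'
#' The boxcar smoothing applied by common instrument software: each point is
#' replaced by the unweighted mean of a window of neighbouring points. Odd
#' windows are centered on the point; even windows are trailing (the point and
#' the `window - 1` preceding points), so "two-point" smoothing averages each
#' point with its predecessor. Windows are truncated at the edges and the
#' output has the same length as the input.
#'
#' @param values Numeric vector.
#' @param window Positive integer window size, at most `length(values)`.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' smooth_adjacent_average(c(0, 2, 0, 2), 2)  # trailing means: 0 1 1 1
#' @export
smooth_adjacent_average <- function(values, window) {
  values <- as.numeric(values)
  window <- as.integer(window)
  n <- length(values)
  if (is.na(window) || window < 1) stop("window must be a positive integer")
  if (window > n) stop("window larger than input length")
  if (window == 1) return(values)
  if (window %% 2 == 1) {
    h <- (window - 1L) %/% 2L
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
  } else {
    lo <- pmax(seq_len(n) - (window - 1L), 1L)
    hi <- seq_len(n)
  }
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fit a two-state thermal melt
#'
#' Fits the standard two-state unfolding model with linear folded and
#' unfolded baselines,
#' \deqn{S(T) = (b_N + m_N T) + [(b_U + m_U T) - (b_N + m_N T)]\,\sigma(T),}
#' \deqn{\sigma(T) = 1 / (1 + \exp((T_m - T)/w)),}
#' to a melt curve by nonlinear least squares. `w` sets the transition width
#' (about 4.4 w between 10% and 90% unfolded).
#'
#' Initial values: `Tm` at the temperature of steepest signal change,
#' `w` = 2 degC, baselines from straight lines through the first and last 10%
#' of points. `Tm` is constrained inside the observed temperature range.
#'
#' @param curve A [melt_curve()].
#' @return An object of class `"melt_fit"` with elements `tm_c`,
#'   `transition_width`, `baselines` (named `bN`, `mN`, `bU`, `mU`), `rss`
#'   and the data. Errors with "no transition detected" when no credible
#'   sigmoidal transition exists in the data (e.g. a straight line).
#' @seealso [simulate_melt_curve()] for generating test curves.
#' @export
fit_two_state_melt <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  tc <- curve$temperature_c; y <- curve$signal
  n <- length(tc)
  rng <- diff(range(y))
  if (rng == 0) stop("no transition detected: flat signal")
  # initialization
  n_edge <- max(2L, n %/% 10L)
  pre <- stats::lm.fit(cbind(1, tc[seq_len(n_edge)]), y[seq_len(n_edge)])
  post_i <- seq.int(n - n_edge + 1L, n)
  post <- stats::lm.fit(cbind(1, tc[post_i]), y[post_i])
  dy <- diff(smooth_adjacent_average(y, min(5L, n)))
  tm0 <- tc[which.max(abs(dy))]
  tm0 <- min(max(tm0, tc[2]), tc[n - 1])
  start <- list(bN = pre$coefficients[1], mN = pre$coefficients[2],
                bU = post$coefficients[1], mU = post$coefficients[2],
                tm = tm0, w = 2)
  dat <- data.frame(tc = tc, y = y)
  fit <- try(stats::nls(
    y ~ (bN + mN * tc) +
      ((bU + mU * tc) - (bN + mN * tc)) / (1 + exp((tm - tc) / w)),
    data = dat, start = start, algorithm = "port",
    lower = c(-Inf, -Inf, -Inf, -Inf, min(tc), 0.05),
    upper = c(Inf, Inf, Inf, Inf, max(tc), diff(range(tc))),
    control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    silent = TRUE)
  if (inherits(fit, "try-error")) stop("no transition detected")
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  rss <- sum(res^2)
  amp <- abs((cf["bU"] + cf["mU"] * cf["tm"]) -
             (cf["bN"] + cf["mN"] * cf["tm"]))
  noise <- stats::sd(diff(y)) / sqrt(2)
  # a real transition must dominate both the noise and the overall excursion
  if (cf["tm"] <= min(tc) + 1e-6 || cf["tm"] >= max(tc) - 1e-6 ||
      amp < 0.05 * rng || (noise > 0 && amp < 5 * noise && rss > 0 &&
                           amp < 5 * sqrt(rss / (n - 6)))) {
    stop("no transition detected")
  }
  structure(list(tm_c = unname(cf["tm"]),
                 transition_width = unname(cf["w"]),
                 baselines = c(bN = unname(cf["bN"]), mN = unname(cf["mN"]),
                               bU = unname(cf["bU"]), mU = unname(cf["mU"])),
                 rss = rss, curve = curve, fitted = stats::fitted(fit)),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melt fit: Tm = %.2f degC, width = %.2f degC, RSS = %.3g\n",
              x$tm_c, x$transition_width, x$rss))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm_c = object$tm_c, transition_width = object$transition_width,
    object$baselines)
}

#' @export
predict.melt_fit <- function(object, temperature_c = NULL, ...) {
  tc <- if (is.null(temperature_c)) object$curve$temperature_c
        else temperature_c
  b <- object$baselines
  s <- 1 / (1 + exp((object$tm_c - tc) / object$transition_width))
  (b["bN"] + b["mN"] * tc) +
    ((b["bU"] + b["mU"] * tc) - (b["bN"] + b["mN"] * tc)) * s
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$curve$signal - predict(object)
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$temperature_c, x$curve$signal,
                 xlab = "Temperature (degC)", ylab = "Signal",
                 main = sprintf("Tm = %.1f degC", x$tm_c), ...)
  graphics::lines(x$curve$temperature_c, predict(x), col = 2, lwd = 2)
  invisible(x)
}
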