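#' Column model for fast-exchange monomer-dimer elution
#'
#' Under fast monomer-dimer exchange a self-associating protein elutes as a
#' single peak whose position interpolates (in the log2-mass sense of the
#' calibration) between the monomer and dimer elution volumes. The column
#' model holds those two endpoint volumes and the monomer molecular mass.
#'
#' @param vm_ml Monomer elution volume (mL).
#' @param vd_ml Dimer elution volume (mL); must be smaller than `vm_ml`
#'   (the dimer elutes earlier).
#' @param monomer_mw_kda Monomer molecular mass (kDa), > 0.
#' @return An object of class `"column_model"`.
#' @export
column_model <- function(vm_ml, vd_ml, monomer_mw_kda) {
  if (!is.finite(vm_ml) || !is.finite(vd_ml) || vd_ml >= vm_ml) {
    stop("require vd_ml < vm_ml (dimer elutes earlier)")
  }
  if (!is.finite(monomer_mw_kda) || monomer_mw_kda <= 0) {
    stop("monomer_mw_kda must be > 0")
  }
  structure(list(vm_ml = vm_ml, vd_ml = vd_ml,
                 monomer_mw_kda = monomer_mw_kda),
            class = "column_model")
}

#' @export
print.column_model <- function(x, ...) {
  cat(sprintf("Column model: Vm = %.3f mL, Vd = %.3f mL, monomer %.3f kDa\n",
              x$vm_ml, x$vd_ml, x$monomer_mw_kda))
  invisible(x)
}

#' Percent dimer from elution volume
#'
#' The fast-exchange relation: the effective mass A(1 + \%D/100) together with
#' the log-linear calibration gives
#' \deqn{\%D = 100\,(2^{(V_m - V_e)/(V_m - V_d)} - 1).}
#' Values of `ve_ml` outside `[vd, vm]` give \%D outside `[0, 100]` and are
#' clipped with a warning.
#'
#' @param ve_ml Observed elution volume(s), mL.
#' @param col A [column_model()].
#' @return Percent dimer in `[0, 100]`.
#' @export
percent_dimer_from_elution <- function(ve_ml, col) {
  stopifnot(inherits(col, "column_model"))
  span <- col$vm_ml - col$vd_ml
  if (span == 0) stop("vm_ml equals vd_ml")
  pd <- 100 * (2^((col$vm_ml - ve_ml) / span) - 1)
  if (any(pd < 0 | pd > 100)) {
    warning("elution volume outside [Vd, Vm]; %D clipped to [0, 100]")
    pd <- pmin(pmax(pd, 0), 100)
  }
  pd
}

#' Elution volume from percent dimer
#'
#' Exact inverse of [percent_dimer_from_elution()]:
#' \eqn{V_e = V_m - (V_m - V_d)\log_2(1 + \%D/100)}.
#'
#' @param percent_dimer Percent dimer in `[0, 100]`.
#' @param col A [column_model()].
#' @return Elution volume(s) in mL.
#' @export
elution_volume_from_percent_dimer <- function(percent_dimer, col) {
  stopifnot(inherits(col, "column_model"))
  if (any(percent_dimer < 0 | percent_dimer > 100)) {
    stop("percent_dimer must be in [0, 100]")
  }
  col$vm_ml - (col$vm_ml - col$vd_ml) * log2(1 + percent_dimer / 100)
}

#' Effective molecular mass of the exchange-averaged species
#'
#' MW = A (1 + \%D/100): the apparent mass runs from the monomer mass A at
#' \%D = 0 to the dimer mass 2A at \%D = 100.
#'
#' @param col A [column_model()] supplying the monomer mass A.
#' @param percent_dimer Percent dimer in `[0, 100]`.
#' @return Effective mass in kDa, always in `[A, 2A]`.
#' @export
effective_mw <- function(col, percent_dimer) {
  stopifnot(inherits(col, "column_model"))
  if (any(percent_dimer < 0 | percent_dimer > 100)) {
    stop("percent_dimer must be in [0, 100]")
  }
  col$monomer_mw_kda * (1 + percent_dimer / 100)
}

#' Equilibrium percent dimer at a total concentration
#'
#' Solves the mass-action monomer-dimer equilibrium
#' \eqn{K_d = [M]^2/[D]} with total concentration in dimer equivalents,
#' \eqn{[D_{tot}] = [M]/2 + [D]}, i.e. the unique root in `[0, 100]` of
#' \deqn{K_d = D_{tot} \cdot 0.04\,(100 - \%D)^2 / \%D.}
#' Evaluated in the cancellation-free form
#' \eqn{\%D = 800\,D_{tot} / [(8 D_{tot} + K_d) + \sqrt{K_d(K_d + 16 D_{tot})}]}.
#'
#' @param dtot_uM Total protein concentration(s), uM in dimer equivalents,
#'   > 0.
#' @param kd_uM Dimer dissociation constant, uM, >= 0 (0 means an
#'   infinitely tight dimer, \%D = 100).
#' @return Percent dimer in `[0, 100]`.
#' @examples
#' fraction_dimer(1.2, 1.2)  # %D at Dtot = Kd is 60.96
#' @export
fraction_dimer <- function(dtot_uM, kd_uM) {
  if (any(!is.finite(dtot_uM)) || any(dtot_uM <= 0)) {
    stop("dtot_uM must be > 0")
  }
  if (!is.finite(kd_uM) || kd_uM < 0) stop("kd_uM must be >= 0")
  800 * dtot_uM /
    ((8 * dtot_uM + kd_uM) + sqrt(kd_uM * (kd_uM + 16 * dtot_uM)))
}

#' Manning transform of percent dimer
#'
#' \eqn{y = \log_{10}[\%D / (0.04\,(100-\%D)^2)]}. Plotted against
#' \eqn{\log_{10} D_{tot}} the mass-action model gives a straight line of
#' slope 1, and y = 0 exactly where \eqn{D_{tot} = K_d}.
#'
#' @param percent_dimer Percent dimer strictly inside (0, 100).
#' @return The transform value(s).
#' @export
manning_y <- function(percent_dimer) {
  if (any(percent_dimer <= 0 | percent_dimer >= 100)) {
    stop("excluded point: percent_dimer must be strictly inside (0, 100)")
  }
  log10(percent_dimer / (0.04 * (100 - percent_dimer)^2))
}

#' Build equilibrium points from chromatograms
#'
#' Converts a list of single-peak chromatograms into the concentration /
#' percent-dimer table the Kd estimators consume: each trace yields the peak
#' apex (hence \%D via [percent_dimer_from_elution()]) and the dilution
#' factor FWHM / load volume, which corrects the loaded concentration to the
#' on-column concentration.
#'
#' @param chroms List of [chromatogram()] objects with `loaded_conc_uM` set
#'   (uM, dimer equivalents).
#' @param col A [column_model()].
#' @param smooth_window Smoothing window passed to [peak_metrics()];
#'   default 9 suits finely sampled noisy traces.
#' @param dilution_factor Optional fixed dilution factor overriding the
#'   per-injection FWHM-based estimate.
#' @return Data frame with columns `dtot_loaded_uM`, `dtot_corrected_uM`,
#'   `percent_dimer`, `ve_ml`, `fwhm_ml`, `dilution_factor`.
#' @export
equilibrium_points <- function(chroms, col, smooth_window = 9L,
                               dilution_factor = NULL) {
  stopifnot(inherits(col, "column_model"))
  if (inherits(chroms, "chromatogram")) chroms <- list(chroms)
  rows <- lapply(chroms, function(ch) {
    pm <- peak_metrics(ch, smooth_window = smooth_window)
    dil <- if (is.null(dilution_factor)) pm$dilution_factor
           else dilution_factor
    pd <- suppressWarnings(percent_dimer_from_elution(pm$apex_volume_ml, col))
    data.frame(dtot_loaded_uM = ch$loaded_conc_uM,
               dtot_corrected_uM = ch$loaded_conc_uM / dil,
               percent_dimer = pd,
               ve_ml = pm$apex_volume_ml,
               fwhm_ml = pm$fwhm_ml,
               dilution_factor = dil)
  })
  do.call(rbind, rows)
}

# normalize estimator input to a data.frame with the two required columns
as_equilibrium_table <- function(points) {
  points <- as.data.frame(points)
  need <- c("dtot_corrected_uM", "percent_dimer")
  if (!all(need %in% names(points))) {
    stop("points must have columns dtot_corrected_uM and percent_dimer")
  }
  if (any(points$dtot_corrected_uM <= 0)) {
    stop("dtot_corrected_uM must be > 0")
  }
  points
}

#' Manning log-linear Kd estimator
#'
#' Estimates the dimer dissociation constant from (concentration, \%D)
#' points using the linearization \eqn{\log_{10} K_d = \log_{10} D_{tot} - y}
#' with y the [manning_y()] transform. Points with \%D outside `[1, 99]`
#' carry essentially no information about Kd and are excluded with a
#' warning. With `fix_slope = TRUE` (default) the theoretical slope of 1 is
#' imposed and \eqn{\log_{10} K_d} is the mean of the per-point values; the
#' unconstrained OLS slope is always reported as a diagnostic (a warning is
#' issued when it strays more than 0.15 from 1). With `fix_slope = FALSE`
#' the Kd is read off where the free OLS line crosses y = 0.
#'
#' @param points Data frame with columns `dtot_corrected_uM` and
#'   `percent_dimer` (e.g. from [equilibrium_points()]).
#' @param fix_slope Impose the theoretical slope of 1 (default TRUE).
#' @return An object of class `"kd_fit"`: `kd_uM`, `log_points` (data frame
#'   of `log10_dtot`, `y`), `slope_unconstrained`, `stderr_log_kd`,
#'   `n_points_used`, `method`. Errors with `"no association detected"` when
#'   every point is outside the usable \%D window (the expected outcome for
#'   an obligate monomer).
#' @examples
#' d <- 10^seq(-1, 2, length.out = 8)
#' pts <- data.frame(dtot_corrected_uM = d,
#'                   percent_dimer = fraction_dimer(d, 1.2))
#' fit_kd_manning(pts)
#' @export
fit_kd_manning <- function(points, fix_slope = TRUE) {
  points <- as_equilibrium_table(points)
  use <- points$percent_dimer >= 1 & points$percent_dimer <= 99
  if (!any(use)) {
    stop("no association detected: all points outside %D window [1, 99]")
  }
  if (sum(!use) > 0) {
    warning(sum(!use), " point(s) outside %D window [1, 99] excluded")
  }
  if (sum(use) < 3) {
    # a series that sits essentially below the window is a monomer, not a
    # failed fit: stray near-threshold points from measurement noise are not
    # evidence of association
    if (all(points$percent_dimer < 2)) {
      stop("no association detected: series shows no appreciable dimer")
    }
    stop("need at least 3 usable points")
  }
  x <- log10(points$dtot_corrected_uM[use])
  y <- manning_y(points$percent_dimer[use])
  n <- length(x)
  # closed-form OLS (avoids summary.lm instability warnings on exact lines)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b1 <- sum((x - mx) * (y - my)) / sxx
  b0 <- my - b1 * mx
  slope_free <- b1
  if (abs(slope_free - 1) > 0.15) {
    warning(sprintf(
      "unconstrained Manning slope %.3f deviates from the theoretical 1",
      slope_free))
  }
  if (fix_slope) {
    lk_i <- x - y
    log_kd <- mean(lk_i)
    se <- stats::sd(lk_i) / sqrt(n)
  } else {
    log_kd <- -b0 / b1
    s2 <- sum((y - b0 - b1 * x)^2) / (n - 2)
    vb1 <- s2 / sxx
    vb0 <- s2 * (1 / n + mx^2 / sxx)
    cb01 <- -s2 * mx / sxx
    g <- c(-1 / b1, b0 / b1^2)  # delta method for -b0/b1
    se <- sqrt(g[1]^2 * vb0 + 2 * g[1] * g[2] * cb01 + g[2]^2 * vb1)
  }
  structure(list(kd_uM = 10^log_kd, log_kd = log_kd,
                 log_points = data.frame(log10_dtot = x, y = y),
                 slope_unconstrained = slope_free,
                 stderr_log_kd = if (is.finite(se)) se else 0,
                 n_points_used = n, fix_slope = fix_slope,
                 method = "manning"),
            class = "kd_fit")
}

#' Direct hyperbolic Kd estimator
#'
#' Fits the mass-action curve \%D = [fraction_dimer()]\eqn{(D_{tot}; K_d)}
#' to the points by least squares in \eqn{\log_{10} K_d}, the direct
#' (non-linearized) counterpart of [fit_kd_manning()]. The Manning estimate
#' brackets the one-dimensional search.
#'
#' @param points Data frame with columns `dtot_corrected_uM` and
#'   `percent_dimer`, at least 4 rows.
#' @return A `"kd_fit"` object (`method = "hyperbolic"`). If the optimum
#'   sticks to the search boundary the fit is declared non-converged and the
#'   error carries the Manning estimate in its `manning_kd_uM` field.
#' @export
fit_kd_hyperbolic <- function(points) {
  points <- as_equilibrium_table(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  d <- points$dtot_corrected_uM
  pd <- points$percent_dimer
  init <- tryCatch(suppressWarnings(fit_kd_manning(points)),
                   error = function(e) NULL)
  centre <- if (!is.null(init)) init$log_kd else mean(log10(d))
  lo <- min(centre - 4, log10(min(d)) - 4)
  hi <- max(centre + 4, log10(max(d)) + 4)
  rss_fn <- function(lk) sum((pd - fraction_dimer(d, 10^lk))^2)
  opt <- stats::optimize(rss_fn, c(lo, hi), tol = 1e-10)
  lk <- opt$minimum
  if (lk <= lo + 1e-6 || lk >= hi - 1e-6) {
    cond <- simpleError("hyperbolic Kd fit did not converge")
    cond$manning_kd_uM <- if (!is.null(init)) init$kd_uM else NA_real_
    stop(cond)
  }
  # curvature-based standard error on log10 Kd
  h <- 1e-4
  d2 <- (rss_fn(lk + h) - 2 * opt$objective + rss_fn(lk - h)) / h^2
  sigma2 <- opt$objective / max(1, length(d) - 1)
  se <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  usable <- pd > 0 & pd < 100
  y <- rep(NA_real_, length(d))
  y[usable] <- manning_y(pd[usable])
  structure(list(kd_uM = 10^lk, log_kd = lk,
                 log_points = data.frame(log10_dtot = log10(d), y = y),
                 slope_unconstrained = if (!is.null(init))
                   init$slope_unconstrained else NA_real_,
                 stderr_log_kd = se, n_points_used = length(d),
                 fix_slope = NA, method = "hyperbolic", rss = opt$objective),
            class = "kd_fit")
}

#' Fit a dimer dissociation constant from SEC chromatograms
#'
#' End-to-end estimator: peak metrics and dilution correction for each
#' chromatogram ([equilibrium_points()]), then the Manning or hyperbolic Kd
#' fit.
#'
#' @param chroms List of [chromatogram()] objects.
#' @param col A [column_model()].
#' @param method `"manning"` (default) or `"hyperbolic"`.
#' @param fix_slope Passed to [fit_kd_manning()].
#' @param smooth_window,dilution_factor Passed to [equilibrium_points()].
#' @return A `"kd_fit"` object carrying the point table in `$points`.
#' @export
fit_kd_sec <- function(chroms, col, method = c("manning", "hyperbolic"),
                       fix_slope = TRUE, smooth_window = 9L,
                       dilution_factor = NULL) {
  method <- match.arg(method)
  pts <- equilibrium_points(chroms, col, smooth_window = smooth_window,
                            dilution_factor = dilution_factor)
  fit <- if (method == "manning") fit_kd_manning(pts, fix_slope = fix_slope)
         else fit_kd_hyperbolic(pts)
  fit$points <- pts
  fit
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Dimer dissociation constant (%s%s): Kd = %.4g uM\n",
              x$method,
              if (identical(x$fix_slope, TRUE)) ", slope fixed to 1" else "",
              x$kd_uM))
  cat(sprintf("  n = %d points, se(log10 Kd) = %.3g, free slope = %.3f\n",
              x$n_points_used, x$stderr_log_kd, x$slope_unconstrained))
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  ci <- 10^(object$log_kd + c(-1.96, 1.96) * object$stderr_log_kd)
  out <- list(kd_uM = object$kd_uM, ci95_uM = ci,
              slope_unconstrained = object$slope_unconstrained,
              stderr_log_kd = object$stderr_log_kd,
              n_points_used = object$n_points_used, method = object$method)
  class(out) <- "summary.kd_fit"
  out
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  cat(sprintf("Kd = %.4g uM (95%% CI %.4g-%.4g), %s estimator, n = %d\n",
              x$kd_uM, x$ci95_uM[1], x$ci95_uM[2], x$method,
              x$n_points_used))
  cat(sprintf("Unconstrained Manning slope: %.3f (theory: 1)\n",
              x$slope_unconstrained))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd_uM = object$kd_uM, log10_kd = object$log_kd)
}

#' @export
predict.kd_fit <- function(object, dtot_uM, ...) {
  fraction_dimer(dtot_uM, object$kd_uM)
}

#' @export
plot.kd_fit <- function(x, ...) {
  lp <- x$log_points[is.finite(x$log_points$y), ]
  graphics::plot(lp$log10_dtot, lp$y,
                 xlab = expression(log[10] ~ "[D"[tot] * "] (uM)"),
                 ylab = expression(log[10] ~ "(%D / 0.04(100-%D)"^2 * ")"),
                 main = sprintf("Manning plot, Kd = %.3g uM", x$kd_uM), ...)
  graphics::abline(a = -x$log_kd, b = 1, col = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
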