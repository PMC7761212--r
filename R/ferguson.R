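#' Retardation coefficient from a Ferguson plot
#'
#' For one protein run on native gels of several acrylamide concentrations,
#' fits 100 * log10(100 * Rf) against \%T by ordinary least squares and
#' returns the retardation coefficient Kr = -slope. A species that is not
#' sieved by the gel (constant or increasing mobility with \%T) gives
#' Kr <= 0 and a warning.
#'
#' @param percent_t Gel concentrations (\%T), at least 3 distinct values.
#' @param rf Relative mobilities in (0, 1], same length.
#' @return Kr (numeric scalar).
#' @export
retardation_coefficient <- function(percent_t, rf) {
  if (length(percent_t) != length(rf)) stop("percent_t and rf lengths differ")
  if (length(unique(percent_t)) < 3) {
    stop("need at least 3 distinct %T values")
  }
  if (any(rf <= 0 | rf > 1)) stop("rf must be in (0, 1]")
  fit <- stats::lm(I(100 * log10(100 * rf)) ~ percent_t)
  kr <- -unname(stats::coef(fit)[2])
  if (kr <= 1e-10) warning("non-sieving species: Kr <= 0")
  kr
}

#' Ferguson standard curve
#'
#' Fits log10(Kr) against log10(MW) for the standards, the log-log line used
#' to convert a retardation coefficient into a molecular mass. Standards with
#' Kr <= 0 are excluded with a warning.
#'
#' @param standards Data frame with columns `mw_kda` and `kr` (and optionally
#'   `protein_id`); at least 3 usable standards.
#' @return An object of class `"ferguson_curve"` with `slope`, `intercept`
#'   (both on the log10-log10 scale), `r_squared` and the standards used.
#' @export
fit_ferguson_standard_curve <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("mw_kda", "kr") %in% names(standards))) {
    stop("standards must have columns mw_kda and kr")
  }
  bad <- standards$kr <= 0
  if (any(bad)) {
    warning(sum(bad), " standard(s) with Kr <= 0 excluded")
    standards <- standards[!bad, , drop = FALSE]
  }
  if (nrow(standards) < 3) stop("need at least 3 standards with Kr > 0")
  fit <- stats::lm(log10(kr) ~ log10(mw_kda), data = standards)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r_squared(fit), standards = standards),
            class = "ferguson_curve")
}

#' @export
print.ferguson_curve <- function(x, ...) {
  cat(sprintf(
    "Ferguson standard curve: log10 Kr = %.4f %+.4f * log10 MW(kDa)  (R^2 = %.4f)\n",
    x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.ferguson_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Molecular mass from a retardation coefficient
#'
#' Inverts the Ferguson standard curve:
#' MW = 10^((log10 Kr - intercept) / slope).
#'
#' @param curve A [fit_ferguson_standard_curve()] object.
#' @param kr Retardation coefficient(s), > 0.
#' @return Molecular mass(es) in kDa.
#' @export
estimate_mw_ferguson <- function(curve, kr) {
  stopifnot(inherits(curve, "ferguson_curve"))
  if (any(kr <= 0)) stop("kr must be > 0")
  10^((log10(kr) - curve$intercept) / curve$slope)
}

#' @export
predict.ferguson_curve <- function(object, kr, ...) {
  estimate_mw_ferguson(object, kr)
}

#' Full Ferguson-plot analysis of a gel mobility table
#'
#' Runs the complete native-PAGE pipeline: a retardation coefficient per
#' protein from its Rf-vs-\%T series, a log-log standard curve over the
#' proteins with known mass, and a mass estimate for every protein not in
#' the standards table.
#'
#' @param gel Data frame with columns `protein_id`, `percent_t`, `rf`
#'   (each protein at >= 3 \%T values).
#' @param standards Data frame with columns `protein_id` and `mw_kda`.
#' @return An object of class `"ferguson_fit"` with `kr_by_protein` (named
#'   numeric), `curve` (the standard curve) and `estimates` (data frame
#'   `protein_id`, `kr`, `mw_kda` for the unknowns).
#' @examples
#' std <- data.frame(protein_id = c("a", "b", "c", "d"),
#'                   mw_kda = c(14.2, 29, 66, 132))
#' gel <- simulate_gel_runs(std, unknown_mw_kda = 17.9)
#' ferguson_analysis(gel, std)
#' @export
ferguson_analysis <- function(gel, standards) {
  gel <- as.data.frame(gel)
  standards <- as.data.frame(standards)
  if (!all(c("protein_id", "percent_t", "rf") %in% names(gel))) {
    stop("gel must have columns protein_id, percent_t, rf")
  }
  ids <- unique(gel$protein_id)
  kr <- vapply(ids, function(id) {
    g <- gel[gel$protein_id == id, ]
    retardation_coefficient(g$percent_t, g$rf)
  }, numeric(1))
  names(kr) <- ids
  std_ids <- intersect(ids, standards$protein_id)
  std_tab <- data.frame(
    protein_id = std_ids,
    mw_kda = standards$mw_kda[match(std_ids, standards$protein_id)],
    kr = kr[std_ids])
  curve <- fit_ferguson_standard_curve(std_tab)
  unk_ids <- setdiff(ids, standards$protein_id)
  estimates <- data.frame(
    protein_id = unk_ids,
    kr = unname(kr[unk_ids]),
    mw_kda = if (length(unk_ids))
      estimate_mw_ferguson(curve, kr[unk_ids]) else numeric(0))
  structure(list(kr_by_protein = kr, curve = curve, estimates = estimates),
            class = "ferguson_fit")
}

#' @export
print.ferguson_fit <- function(x, ...) {
  print(x$curve)
  if (nrow(x$estimates)) {
    for (i in seq_len(nrow(x$estimates))) {
      cat(sprintf("  %s: Kr = %.3f -> %.2f kDa\n",
                  x$estimates$protein_id[i], x$estimates$kr[i],
                  x$estimates$mw_kda[i]))
    }
  }
  invisible(x)
}

#' @export
coef.ferguson_fit <- function(object, ...) coef(object$curve)
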