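#' Built-in deoxy coordination reference shapes
#'
#' Deterministic synthetic endmember spectra on a 450-650 nm grid (0.5 nm
#' step), built from fixed sums of Gaussian bands and area-normalized. The
#' hexacoordinate shape has the resolved alpha (~557 nm) and beta (~528 nm)
#' bands of a bis-histidyl deoxy heme; the pentacoordinate shape is the
#' single broad band of a five-coordinate deoxy heme. Their A555/A540 ratios
#' differ by well over 0.2, so the pair is usable for both the ratio and
#' the unmixing estimators. These are synthetic stand-ins with plausible
#' band structure, not measured spectra.
#'
#' @return A [reference_pair()] (area normalization).
#' @examples
#' refs <- make_reference_shapes()
#' band_ratio(refs$hexa); band_ratio(refs$penta)
#' @export
make_reference_shapes <- function() {
  wl <- seq(450, 650, by = 0.5)
  gauss <- function(mu, sig, amp) amp * exp(-(wl - mu)^2 / (2 * sig^2))
  # hexa: resolved alpha/beta bands with a genuine trough near 540 nm
  hexa <- gauss(557, 6, 1.0) + gauss(527, 7, 0.8) + gauss(502, 45, 0.22)
  # penta: one broad band centred just past 555 nm
  penta <- gauss(558, 18, 1.0) + gauss(515, 40, 0.2)
  reference_pair(spectrum(wl, hexa, meta = list(species = "hexa_reference")),
                 spectrum(wl, penta, meta = list(species = "penta_reference")),
                 normalization = "area")
}

# deterministic child seed for item i of a master-seeded batch
child_seed <- function(seed, i) {
  (as.integer(seed) %% 2147480000L + 7919L * as.integer(i)) %% 2147483647L
}

#' SEC simulation preset
#'
#' Bundles the ground-truth parameters of a synthetic monomer-dimer SEC
#' concentration series: the dissociation constant (or `"monomer_only"` for
#' an obligate monomer), the column model, dilution factor, concentration
#' range and noise level.
#'
#' @param name Preset name.
#' @param kd_uM Dissociation constant in uM, or the string
#'   `"monomer_only"`.
#' @param column A [column_model()].
#' @param dilution_factor On-column dilution factor (> 1).
#' @param conc_range_uM Length-2 loaded-concentration range (uM, dimer
#'   equivalents), low < high.
#' @param n_points Number of series points (>= 3).
#' @param noise_frac Additive noise s.d. as a fraction of peak height.
#' @param load_volume_ml Injection volume (mL).
#' @return An object of class `"sec_preset"`.
#' @export
sec_preset <- function(name, kd_uM, column, dilution_factor,
                       conc_range_uM, n_points = 12L, noise_frac = 0.01,
                       load_volume_ml = 0.1) {
  monomer_only <- identical(kd_uM, "monomer_only")
  if (!monomer_only && (!is.numeric(kd_uM) || kd_uM < 0)) {
    stop("kd_uM must be >= 0 or \"monomer_only\"")
  }
  stopifnot(inherits(column, "column_model"),
            dilution_factor > 1,
            length(conc_range_uM) == 2,
            conc_range_uM[1] < conc_range_uM[2],
            n_points >= 3, noise_frac >= 0, load_volume_ml > 0)
  structure(list(name = name, kd_uM = kd_uM, monomer_only = monomer_only,
                 column = column, dilution_factor = dilution_factor,
                 conc_range_uM = conc_range_uM, n_points = as.integer(n_points),
                 noise_frac = noise_frac, load_volume_ml = load_volume_ml),
            class = "sec_preset")
}

#' @export
print.sec_preset <- function(x, ...) {
  kd <- if (x$monomer_only) "monomer only" else sprintf("Kd = %g uM", x$kd_uM)
  cat(sprintf(
    "SEC preset \"%s\": %s, %g-%g uM (%d pts), dilution %g, noise %g\n",
    x$name, kd, x$conc_range_uM[1], x$conc_range_uM[2], x$n_points,
    x$dilution_factor, x$noise_frac))
  invisible(x)
}

#' Built-in SEC presets
#'
#' The four study conditions: ferrous-oxy wild type (Kd 1.2 uM, 0.07-85 uM
#' series, dilution factor 8), ferric wild type (Kd 11 uM, 0.1-300 uM,
#' dilution 8), the ferrous-oxy T45A interface mutant (Kd 876 uM,
#' 1-1000 uM, dilution 7) and the obligate monomer class-2 protein
#' (0.1-60 uM, dilution 6). All use 12 log-spaced concentrations and 1%
#' peak noise on a default column with Vm = 8.719 mL, Vd = 7.214 mL
#' (a synthetic stand-in geometry; real column volumes are instrument
#' specific and configurable).
#'
#' @param name Optional preset name (`"ahb1_oxy"`, `"ahb1_ferric"`,
#'   `"ahb1_t45a"`, `"ahb2"`); omit for the full named list.
#' @return A `"sec_preset"` or a named list of them.
#' @export
sec_presets <- function(name = NULL) {
  col1 <- column_model(8.719, 7.214, 18.034)
  col2 <- column_model(8.719, 7.214, 17.871)
  presets <- list(
    ahb1_oxy = sec_preset("ahb1_oxy", 1.2, col1, 8, c(0.07, 85)),
    ahb1_ferric = sec_preset("ahb1_ferric", 11, col1, 8, c(0.1, 300)),
    ahb1_t45a = sec_preset("ahb1_t45a", 876, col1, 7, c(1, 1000)),
    ahb2 = sec_preset("ahb2", "monomer_only", col2, 6, c(0.1, 60)))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown SEC preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  }
  presets[[name]]
}

#' Simulate one SEC chromatogram
#'
#' Forward model of a fast-exchange monomer-dimer elution: the loaded
#' concentration is diluted on-column by the preset dilution factor, the
#' equilibrium percent dimer follows [fraction_dimer()] at that on-column
#' concentration (0 for a monomer-only preset), the apex sits at
#' [elution_volume_from_percent_dimer()], and the peak is a Gaussian with
#' FWHM = dilution_factor * load_volume and height proportional to the
#' loaded concentration, plus seeded additive Gaussian noise
#' (s.d. = noise_frac * height).
#'
#' @param dtot_loaded_uM Loaded concentration (uM, dimer equivalents), > 0.
#' @param preset A [sec_preset()].
#' @param seed Integer seed (the generator is a pure function of its
#'   arguments including the seed).
#' @param volume_step_ml Trace sampling step (mL).
#' @return A [chromatogram()] whose `meta` records the preset name, the
#'   true percent dimer and apex, and the seed.
#' @export
simulate_chromatogram <- function(dtot_loaded_uM, preset, seed = 1L,
                                  volume_step_ml = 0.01) {
  stopifnot(inherits(preset, "sec_preset"))
  if (!is.finite(dtot_loaded_uM) || dtot_loaded_uM <= 0) {
    stop("dtot_loaded_uM must be > 0")
  }
  col <- preset$column
  dtot_col <- dtot_loaded_uM / preset$dilution_factor
  pd <- if (preset$monomer_only) 0 else fraction_dimer(dtot_col, preset$kd_uM)
  apex <- elution_volume_from_percent_dimer(pd, col)
  fwhm <- preset$dilution_factor * preset$load_volume_ml
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  v <- seq(col$vd_ml - 1.6, col$vm_ml + 1.6, by = volume_step_ml)
  height <- dtot_loaded_uM
  signal <- height * exp(-(v - apex)^2 / (2 * sigma^2))
  if (preset$noise_frac > 0) {
    set.seed(as.integer(seed) %% 2147483647L)
    signal <- signal + stats::rnorm(length(v), 0, preset$noise_frac * height)
  }
  chromatogram(v, signal, load_volume_ml = preset$load_volume_ml,
               loaded_conc_uM = dtot_loaded_uM,
               meta = list(preset = preset$name, true_percent_dimer = pd,
                           true_apex_ml = apex, seed = seed))
}

#' Simulate a SEC concentration series
#'
#' Generates `n_points` chromatograms at log-spaced loaded concentrations
#' across the preset's range; per-trace noise seeds are derived
#' deterministically from the master seed.
#'
#' @param preset A [sec_preset()].
#' @param seed Master integer seed.
#' @return List of [chromatogram()] objects (low to high concentration).
#' @examples
#' chroms <- simulate_sec_series(sec_presets("ahb1_oxy"), seed = 1)
#' fit_kd_sec(chroms, sec_presets("ahb1_oxy")$column)
#' @export
simulate_sec_series <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "sec_preset"))
  loads <- 10^seq(log10(preset$conc_range_uM[1]),
                  log10(preset$conc_range_uM[2]),
                  length.out = preset$n_points)
  lapply(seq_along(loads), function(i) {
    simulate_chromatogram(loads[i], preset, seed = child_seed(seed, i))
  })
}

#' Simulate ideal Ferguson gel runs
#'
#' Generates an Rf table for standards plus one unknown under ideal Ferguson
#' behavior: Rf = Rf0 * 10^(-Kr * \%T / 100) with a power-law size
#' dependence Kr = a * MW^b, optional multiplicative log-normal noise, Rf
#' clipped to (0, 1].
#'
#' @param standards Data frame with columns `protein_id` and `mw_kda`.
#' @param unknown_mw_kda True mass of the unknown (kDa); its rows carry
#'   `protein_id = "unknown"`.
#' @param percent_t_list Gel concentrations (\%T), at least 3.
#' @param noise_frac Log-normal noise s.d. (0 for noiseless).
#' @param seed Integer seed.
#' @param a,b,rf0 Mobility-model constants.
#' @return Data frame `protein_id`, `percent_t`, `rf` (a Ferguson table,
#'   directly consumable by [ferguson_analysis()]).
#' @export
simulate_gel_runs <- function(standards, unknown_mw_kda,
                              percent_t_list = c(8, 9, 10, 12),
                              noise_frac = 0, seed = 1L,
                              a = 0.5, b = 0.7, rf0 = 0.9) {
  standards <- as.data.frame(standards)
  if (length(percent_t_list) < 3) stop("need at least 3 %T values")
  ids <- c(as.character(standards$protein_id), "unknown")
  mws <- c(standards$mw_kda, unknown_mw_kda)
  tab <- expand.grid(protein_id = ids, percent_t = percent_t_list,
                     stringsAsFactors = FALSE)
  tab$mw <- mws[match(tab$protein_id, ids)]
  kr <- a * tab$mw^b
  rf <- rf0 * 10^(-kr * tab$percent_t / 100)
  if (noise_frac > 0) {
    set.seed(as.integer(seed) %% 2147483647L)
    rf <- rf * exp(stats::rnorm(length(rf), 0, noise_frac))
  }
  tab$rf <- pmin(rf, 1)
  tab <- tab[order(tab$protein_id, tab$percent_t), c("protein_id", "percent_t", "rf")]
  rownames(tab) <- NULL
  tab
}

#' Simulate a deoxy visible spectrum
#'
#' Two-endmember mixture of the built-in (or supplied) reference shapes:
#' scale * (f * penta + (1 - f) * hexa), plus seeded additive Gaussian
#' noise with s.d. = noise_frac * max value.
#'
#' @param f_penta Pentacoordinate fraction in `[0, 1]`.
#' @param scale Positive overall scale (absorbs concentration/pathlength).
#' @param noise_frac Noise fraction (0 for noiseless).
#' @param seed Integer seed.
#' @param refs A [reference_pair()]; default [make_reference_shapes()].
#' @return A [spectrum()] whose `meta` records the truth.
#' @export
simulate_deoxy_spectrum <- function(f_penta, scale = 1, noise_frac = 0,
                                    seed = 1L, refs = make_reference_shapes()) {
  if (f_penta < 0 || f_penta > 1) stop("f_penta must be in [0, 1]")
  if (scale <= 0) stop("scale must be > 0")
  wl <- refs$hexa$wavelength_nm
  pen <- stats::approx(refs$penta$wavelength_nm, refs$penta$value, xout = wl)$y
  val <- scale * (f_penta * pen + (1 - f_penta) * refs$hexa$value)
  if (noise_frac > 0) {
    set.seed(as.integer(seed) %% 2147483647L)
    val <- val + stats::rnorm(length(val), 0, noise_frac * max(val))
  }
  spectrum(wl, val, meta = list(true_f_penta = f_penta, scale = scale,
                                seed = seed))
}

#' Coordination-series presets
#'
#' Anchor maps of pentacoordinate fraction versus concentration for the two
#' study conditions: the wild-type series rising from 13% at 1 uM to 65% at
#' 190 uM (pentacoordination coupled to dimerization), and the T45A series
#' flat at 26% from 0.7 to 350 uM. Between anchors f is interpolated
#' linearly in log10 concentration and clamped at the ends.
#'
#' @param name Optional preset name (`"wild_type"`, `"t45a"`); omit for the
#'   full list.
#' @return A `"coordination_preset"` (fields `name`, `f_map`, `noise_frac`)
#'   or a named list of them.
#' @export
coordination_presets <- function(name = NULL) {
  presets <- list(
    wild_type = structure(list(
      name = "wild_type",
      f_map = data.frame(conc_uM = c(1, 190), f_penta = c(0.13, 0.65)),
      noise_frac = 0.005), class = "coordination_preset"),
    t45a = structure(list(
      name = "t45a",
      f_map = data.frame(conc_uM = c(0.7, 350), f_penta = c(0.26, 0.26)),
      noise_frac = 0.005), class = "coordination_preset"))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown coordination preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  }
  presets[[name]]
}

#' @export
print.coordination_preset <- function(x, ...) {
  cat(sprintf(
    "Coordination preset \"%s\": f %.2f@%g uM -> %.2f@%g uM, noise %g\n",
    x$name, x$f_map$f_penta[1], x$f_map$conc_uM[1],
    x$f_map$f_penta[nrow(x$f_map)], x$f_map$conc_uM[nrow(x$f_map)],
    x$noise_frac))
  invisible(x)
}

#' Ground-truth pentacoordinate fraction of a preset
#'
#' @param preset A [coordination_presets()] entry.
#' @param conc_uM Concentration(s), uM.
#' @return f interpolated linearly in log10 concentration, clamped at the
#'   anchor ends.
#' @export
preset_f_penta <- function(preset, conc_uM) {
  stopifnot(inherits(preset, "coordination_preset"))
  stats::approx(log10(preset$f_map$conc_uM), preset$f_map$f_penta,
                xout = log10(conc_uM), rule = 2)$y
}

#' Simulate a deoxy concentration series
#'
#' One spectrum per concentration at the preset's ground-truth f and noise,
#' with per-spectrum seeds derived from the master seed.
#'
#' @param preset A [coordination_presets()] entry.
#' @param conc_uM Concentrations (uM); default 8 log-spaced points across
#'   the preset's anchor range.
#' @param seed Master integer seed.
#' @param refs Reference shapes used for mixing.
#' @return List of `list(conc_uM =, spectrum =)` entries, consumable by
#'   [coordination_series()].
#' @export
simulate_coordination_series <- function(preset, conc_uM = NULL, seed = 1L,
                                         refs = make_reference_shapes()) {
  stopifnot(inherits(preset, "coordination_preset"))
  if (is.null(conc_uM)) {
    conc_uM <- 10^seq(log10(min(preset$f_map$conc_uM)),
                      log10(max(preset$f_map$conc_uM)), length.out = 8)
  }
  lapply(seq_along(conc_uM), function(i) {
    f <- preset_f_penta(preset, conc_uM[i])
    sp <- simulate_deoxy_spectrum(f, scale = 1,
                                  noise_frac = preset$noise_frac,
                                  seed = child_seed(seed, i), refs = refs)
    sp$meta$conc_uM <- conc_uM[i]
    list(conc_uM = conc_uM[i], spectrum = sp)
  })
}

#' Simulate a two-state thermal melt curve
#'
#' Generates a CD melt trace on a 20-100 degC grid (0.25 degC step) from the
#' two-state sigmoid of [fit_two_state_melt()], plus seeded Gaussian noise
#' with s.d. = noise_frac * signal range.
#'
#' @param tm_c Midpoint temperature, strictly inside (20, 100) degC.
#' @param width_c Transition width w (degC), > 0.
#' @param baselines Named or positional numeric of length 4:
#'   `bN`, `mN` (folded intercept/slope), `bU`, `mU` (unfolded).
#' @param noise_frac Noise fraction (0 for noiseless).
#' @param seed Integer seed.
#' @return A [melt_curve()].
#' @export
simulate_melt_curve <- function(tm_c, width_c = 2,
                                baselines = c(bN = -10, mN = 0, bU = -1, mU = 0),
                                noise_frac = 0, seed = 1L) {
  if (tm_c <= 20 || tm_c >= 100) stop("tm_c must be strictly inside (20, 100)")
  if (width_c <= 0) stop("width_c must be > 0")
  stopifnot(length(baselines) == 4)
  b <- unname(baselines)
  tc <- seq(20, 100, by = 0.25)
  s <- 1 / (1 + exp((tm_c - tc) / width_c))
  y <- (b[1] + b[2] * tc) + ((b[3] + b[4] * tc) - (b[1] + b[2] * tc)) * s
  if (noise_frac > 0) {
    set.seed(as.integer(seed) %% 2147483647L)
    y <- y + stats::rnorm(length(y), 0, noise_frac * diff(range(y)))
  }
  melt_curve(tc, y, meta = list(true_tm_c = tm_c, true_width_c = width_c,
                                seed = seed))
}
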