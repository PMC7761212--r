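test_that("band ratio: flat spectra, arithmetic, range errors", {
  wl <- 450:650
  expect_equal(band_ratio(spectrum(wl, rep(0.5, length(wl)))), 1)
  val <- rep(0.5, length(wl))
  val[wl == 555] <- 0.75
  val[wl == 540] <- 0.85
  expect_equal(band_ratio(spectrum(wl, val)), 0.75 / 0.85, tolerance = 1e-10)
  expect_equal(0.75 / 0.85, 0.8824, tolerance = 1e-4)
  expect_error(band_ratio(spectrum(450:550, rep(1, 101))), "outside")
  expect_error(band_ratio(spectrum(wl, rep(0, length(wl)))), "<= 0")
})

test_that("ratio inversion uses absolute reference values, not just ratios", {
  # references sampled at integers with prescribed 555/540 values
  wl <- 450:650
  mk <- function(v555, v540) {
    val <- rep(0.6, length(wl))
    val[wl == 555] <- v555
    val[wl == 540] <- v540
    spectrum(wl, val)
  }
  refs <- reference_pair(mk(1.0, 0.8), mk(0.5, 0.9), normalization = "none")
  # forward-mix at f = 0.5: r = (0.5*0.5 + 0.5*1)/(0.5*0.9 + 0.5*0.8)
  r <- 0.75 / 0.85
  expect_equal(penta_fraction_from_ratio(r, refs)$f_penta, 0.5,
               tolerance = 1e-10)
  # endpoints
  expect_equal(penta_fraction_from_ratio(1.0 / 0.8, refs)$f_penta, 0)
  expect_equal(penta_fraction_from_ratio(0.5 / 0.9, refs)$f_penta, 1)
  # out-of-range solutions are clipped with a warning
  expect_warning(est <- penta_fraction_from_ratio(1.4, refs), "clipped")
  expect_true(est$f_penta %in% c(0, 1))
  # indistinguishable references are rejected
  expect_error(
    penta_fraction_from_ratio(1, reference_pair(mk(1, 0.8), mk(0.5, 0.4),
                                                normalization = "none")),
    "indistinguishable")
})

test_that("both estimators are exact on noiseless mixtures over f in 0..1", {
  refs <- make_reference_shapes()
  for (f in seq(0, 1, 0.1)) {
    sp <- simulate_deoxy_spectrum(f, scale = 2.7)
    expect_lt(abs(penta_fraction_unmix(sp, refs)$f_penta - f), 1e-9)
    est_r <- penta_fraction_from_ratio(band_ratio(sp), refs)
    expect_lt(abs(est_r$f_penta - f), 1e-9)
  }
})

test_that("unmixing is invariant to positive rescaling of the input", {
  refs <- make_reference_shapes()
  sp <- simulate_deoxy_spectrum(0.65, scale = 1, noise_frac = 0.005,
                                seed = 5)
  f1 <- penta_fraction_unmix(sp, refs)$f_penta
  sp3 <- spectrum(sp$wavelength_nm, 3 * sp$value)
  expect_equal(penta_fraction_unmix(sp3, refs)$f_penta, f1,
               tolerance = 1e-12)
  # a scaled pure reference is recognised as such
  hx3 <- spectrum(refs$hexa$wavelength_nm, 3 * refs$hexa$value)
  est <- penta_fraction_unmix(hx3, refs)
  expect_equal(est$f_penta, 0)
  expect_lt(est$residual, 1e-10)
})

test_that("unmixing contracts: window width and coverage", {
  refs <- make_reference_shapes()
  sp <- simulate_deoxy_spectrum(0.3)
  expect_error(penta_fraction_unmix(sp, refs, window_nm = c(540, 550)),
               "20 nm")
  expect_error(penta_fraction_unmix(spectrum(450:550, rep(1, 101)), refs),
               "cover")
})

test_that("ratio and unmix estimates agree under 0.5% noise", {
  refs <- make_reference_shapes()
  for (f in c(0.26, 0.65)) {
    d <- vapply(1:20, function(s) {
      sp <- simulate_deoxy_spectrum(f, scale = 1, noise_frac = 0.005,
                                    seed = s)
      penta_fraction_unmix(sp, refs)$f_penta -
        suppressWarnings(penta_fraction_from_ratio(band_ratio(sp),
                                                   refs))$f_penta
    }, numeric(1))
    expect_lt(median(abs(d)), 0.02)
  }
})

test_that("stochastic unmix recovery at f = 0.26 with 0.5% noise", {
  refs <- make_reference_shapes()
  est <- vapply(1:20, function(s) {
    penta_fraction_unmix(simulate_deoxy_spectrum(0.26, noise_frac = 0.005,
                                                 seed = s), refs)$f_penta
  }, numeric(1))
  expect_equal(median(est), 0.26, tolerance = 0.02 / 0.26)
})

test_that("coordination series: monotone wild type, flat mutant, errors kept", {
  refs <- make_reference_shapes()
  wt <- coordination_presets("wild_type")
  series <- simulate_coordination_series(wt, seed = 2)
  res <- coordination_series(series, refs)
  expect_equal(nrow(res), 8)
  expect_true(all(diff(res$f_penta) > -0.02))  # monotone up to noise
  expect_equal(res$f_penta[1], 0.13, tolerance = 0.03 / 0.13)
  expect_equal(res$f_penta[8], 0.65, tolerance = 0.03 / 0.65)

  t45a <- coordination_presets("t45a")
  res2 <- coordination_series(
    simulate_coordination_series(t45a, conc_uM = c(0.7, 10, 100, 350),
                                 seed = 3), refs)
  expect_lt(diff(range(res2$f_penta)), 0.04)

  # a broken spectrum is reported per-entry, series continues
  series[[2]]$spectrum <- spectrum(450:550, rep(1, 101))
  res3 <- coordination_series(series, refs)
  expect_true(is.na(res3$f_penta[2]))
  expect_match(res3$error[2], "cover")
  expect_equal(sum(is.na(res3$f_penta)), 1)

  expect_error(coordination_series(series[1], refs), "at least 2")
})
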