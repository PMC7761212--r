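test_that("reference shapes are normalized, separable and deterministic", {
  refs <- make_reference_shapes()
  area <- function(s) {
    x <- s$wavelength_nm; y <- s$value
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
  expect_equal(area(refs$hexa), 1, tolerance = 1e-9)
  expect_equal(area(refs$penta), 1, tolerance = 1e-9)
  expect_gt(abs(band_ratio(refs$hexa) - band_ratio(refs$penta)), 0.2)
  refs2 <- make_reference_shapes()
  expect_identical(refs$hexa$value, refs2$hexa$value)
  expect_identical(refs$penta$value, refs2$penta$value)
})

test_that("preset registry carries the study conditions", {
  ps <- sec_presets()
  expect_named(ps, c("ahb1_oxy", "ahb1_ferric", "ahb1_t45a", "ahb2"))
  expect_equal(ps$ahb1_oxy$kd_uM, 1.2)
  expect_equal(ps$ahb1_oxy$conc_range_uM, c(0.07, 85))
  expect_equal(ps$ahb1_oxy$dilution_factor, 8)
  expect_equal(ps$ahb1_ferric$kd_uM, 11)
  expect_equal(ps$ahb1_t45a$kd_uM, 876)
  expect_equal(ps$ahb1_t45a$dilution_factor, 7)
  expect_true(ps$ahb2$monomer_only)
  expect_equal(ps$ahb2$dilution_factor, 6)
  expect_error(sec_presets("nope"), "unknown")

  cp <- coordination_presets()
  expect_named(cp, c("wild_type", "t45a"))
  expect_equal(preset_f_penta(cp$wild_type, c(1, 190)), c(0.13, 0.65))
  expect_equal(preset_f_penta(cp$t45a, c(0.7, 350)), c(0.26, 0.26))
})

test_that("simulated chromatograms follow the forward model limits", {
  p <- sec_presets("ahb1_oxy")
  col <- p$column
  noiseless <- p
  noiseless$noise_frac <- 0
  # very dilute: essentially all monomer
  lo <- simulate_chromatogram(0.01, noiseless)
  expect_lt(abs(peak_metrics(lo)$apex_volume_ml - col$vm_ml), 0.01)
  # very concentrated: essentially all dimer
  hi <- simulate_chromatogram(1e4, noiseless)
  expect_lt(abs(peak_metrics(hi)$apex_volume_ml - col$vd_ml), 0.02)
  # obligate monomer never leaves Vm
  m <- sec_presets("ahb2")
  m$noise_frac <- 0
  for (load in c(0.1, 5, 60)) {
    ch <- simulate_chromatogram(load, m)
    expect_equal(ch$meta$true_percent_dimer, 0)
    expect_equal(ch$meta$true_apex_ml, m$column$vm_ml)
  }
  expect_error(simulate_chromatogram(-1, p), "dtot")
})

test_that("simulated series are seeded, reproducible and monotone", {
  p <- sec_presets("ahb1_oxy")
  s1 <- simulate_sec_series(p, seed = 1)
  s1b <- simulate_sec_series(p, seed = 1)
  expect_identical(s1[[3]]$signal, s1b[[3]]$signal)
  s2 <- simulate_sec_series(p, seed = 2)
  expect_false(identical(s1[[3]]$signal, s2[[3]]$signal))
  # noiseless apex strictly decreases with load
  expect_true(all(diff(vapply(s1, function(ch) ch$meta$true_apex_ml,
                              numeric(1))) < 0))
  expect_length(s1, 12)
})

test_that("gel, spectrum and melt generators are seeded pure functions", {
  std <- data.frame(protein_id = c("a", "b", "c"), mw_kda = c(14.2, 29, 66))
  g1 <- simulate_gel_runs(std, 18, noise_frac = 0.01, seed = 9)
  expect_identical(g1, simulate_gel_runs(std, 18, noise_frac = 0.01, seed = 9))
  expect_true(all(g1$rf > 0 & g1$rf <= 1))

  sp1 <- simulate_deoxy_spectrum(0.4, noise_frac = 0.01, seed = 9)
  expect_identical(sp1$value,
                   simulate_deoxy_spectrum(0.4, noise_frac = 0.01,
                                           seed = 9)$value)
  expect_error(simulate_deoxy_spectrum(1.2), "f_penta")

  m1 <- simulate_melt_curve(65, noise_frac = 0.02, seed = 9)
  expect_identical(m1$signal,
                   simulate_melt_curve(65, noise_frac = 0.02, seed = 9)$signal)
  expect_identical(simulate_melt_curve(65)$signal,
                   simulate_melt_curve(65)$signal)
  expect_error(simulate_melt_curve(10), "tm_c")
})

test_that("the monomer-only preset always yields no association", {
  p <- sec_presets("ahb2")
  for (s in 1:10) {
    expect_error(
      suppressWarnings(fit_kd_sec(simulate_sec_series(p, s), p$column)),
      "no association detected")
  }
})
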