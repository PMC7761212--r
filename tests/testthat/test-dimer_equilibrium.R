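default_col <- function() column_model(8.719, 7.214, 18.034)

# independent root-finding oracle for the mass-action equilibrium:
# bisection on Kd = Dtot * 0.04 * (100 - x)^2 / x over x in (0, 100)
fraction_dimer_bisect <- function(dtot, kd) {
  g <- function(x) dtot * 0.04 * (100 - x)^2 / x - kd
  uniroot(g, c(1e-12, 100 - 1e-12), tol = 1e-12)$root
}

test_that("percent dimer from elution volume hits the endpoints and midpoint", {
  col <- default_col()
  expect_equal(percent_dimer_from_elution(col$vm_ml, col), 0)
  expect_equal(percent_dimer_from_elution(col$vd_ml, col), 100)
  expect_equal(percent_dimer_from_elution(7.9665, col), 100 * (sqrt(2) - 1),
               tolerance = 1e-4)
  expect_warning(pd <- percent_dimer_from_elution(9.5, col), "clipped")
  expect_equal(pd, 0)
  expect_error(column_model(8, 8, 18), "vd_ml < vm_ml")
})

test_that("elution volume and percent dimer are exact inverses", {
  col <- default_col()
  expect_equal(elution_volume_from_percent_dimer(0, col), col$vm_ml)
  expect_equal(elution_volume_from_percent_dimer(100, col), col$vd_ml)
  expect_equal(elution_volume_from_percent_dimer(100 * (sqrt(2) - 1), col),
               7.9665, tolerance = 1e-4)
  pd <- seq(0, 100, length.out = 41)
  back <- percent_dimer_from_elution(
    elution_volume_from_percent_dimer(pd, col), col)
  expect_lt(max(abs(back - pd)), 1e-10)
  expect_error(elution_volume_from_percent_dimer(101, col), "0, 100")
})

test_that("effective mass spans [A, 2A] and matches the printed endpoints", {
  col <- default_col()
  expect_equal(effective_mw(col, 0), 18.034)
  expect_equal(effective_mw(col, 100), 36.068)
  expect_equal(effective_mw(col, 50), 27.051)
  pd <- seq(0, 100, 0.5)
  mw <- effective_mw(col, pd)
  expect_true(all(mw >= col$monomer_mw_kda - 1e-12 &
                  mw <= 2 * col$monomer_mw_kda + 1e-12))
})

test_that("fraction_dimer agrees with the bisection oracle", {
  grid <- expand.grid(dtot = 10^seq(-3, 3, length.out = 13),
                      kd = 10^seq(-3, 4, length.out = 8))
  for (i in seq_len(nrow(grid))) {
    expect_lt(abs(fraction_dimer(grid$dtot[i], grid$kd[i]) -
                  fraction_dimer_bisect(grid$dtot[i], grid$kd[i])),
              1e-6)
  }
})

test_that("fraction_dimer limits and fixed point", {
  expect_equal(fraction_dimer(5, 0), 100)
  expect_lt(fraction_dimer(1e-9, 1), 1e-3)
  # %D at Dtot = Kd is (225 - sqrt(10625)) / 2 for any Kd
  x_star <- (225 - sqrt(10625)) / 2
  for (kd in c(0.01, 1.2, 876)) {
    expect_equal(fraction_dimer(kd, kd), x_star, tolerance = 1e-9)
  }
  expect_equal(x_star, 60.96, tolerance = 1e-2)
  expect_error(fraction_dimer(0, 1), "dtot")
})

test_that("fraction_dimer is monotone in Dtot and Kd, bounded in [0, 100]", {
  d <- 10^seq(-4, 4, length.out = 50)
  for (kd in c(0.1, 11, 1000)) {
    f <- fraction_dimer(d, kd)
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= 0 & f <= 100))
  }
  for (dt in c(0.5, 20)) {
    f <- vapply(c(0.01, 1, 100, 1e4), function(k) fraction_dimer(dt, k),
                numeric(1))
    expect_true(all(diff(f) < 0))
  }
})

test_that("Manning transform: fixed point, arithmetic, domain", {
  expect_equal(manning_y((225 - sqrt(10625)) / 2), 0, tolerance = 1e-12)
  expect_equal(manning_y(50), log10(0.5))
  expect_error(manning_y(100), "excluded")
  expect_error(manning_y(0), "excluded")
})

test_that("Manning estimator round-trips the forward model exactly", {
  for (kd in c(1.2, 876)) {
    rng <- if (kd == 1.2) c(0.07, 85) else c(1, 1000)
    d <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 12)
    pts <- data.frame(dtot_corrected_uM = d,
                      percent_dimer = fraction_dimer(d, kd))
    fit <- suppressWarnings(fit_kd_manning(pts))
    expect_lt(abs(fit$kd_uM / kd - 1), 1e-6)
    expect_equal(fit$slope_unconstrained, 1, tolerance = 1e-6)
    expect_lt(fit$stderr_log_kd, 1e-9)
  }
})

test_that("Manning round trip holds across Kd in [1e-3, 1e4] uM", {
  for (kd in 10^seq(-3, 4)) {
    # noiseless design spanning %D 5-95 around the Kd
    d <- 10^seq(log10(kd) - 1.5, log10(kd) + 1.5, length.out = 9)
    pd <- fraction_dimer(d, kd)
    keep <- pd >= 5 & pd <= 95
    pts <- data.frame(dtot_corrected_uM = d[keep], percent_dimer = pd[keep])
    fit <- fit_kd_manning(pts)
    expect_lt(abs(fit$kd_uM / kd - 1), 1e-6)
    free <- fit_kd_manning(pts, fix_slope = FALSE)
    expect_lt(abs(free$kd_uM / kd - 1), 1e-6)
  }
})

test_that("Manning estimator exclusions and monomer behavior", {
  d <- c(1, 2, 4, 8)
  # all points below the window: an obligate monomer
  expect_error(fit_kd_manning(data.frame(dtot_corrected_uM = d,
                                         percent_dimer = rep(0.5, 4))),
               "no association detected")
  # partial exclusion warns and drops
  pts <- data.frame(dtot_corrected_uM = c(d, 16),
                    percent_dimer = c(fraction_dimer(d, 2), 0.2))
  expect_warning(fit <- fit_kd_manning(pts), "excluded")
  expect_equal(fit$n_points_used, 4)
  # too few informative points
  expect_error(suppressWarnings(
    fit_kd_manning(data.frame(dtot_corrected_uM = d,
                              percent_dimer = c(50, 60, 0.2, 0.3)))),
    "at least 3")
})

test_that("hyperbolic estimator matches Manning on noiseless series", {
  for (kd in c(1.2, 11)) {
    d <- 10^seq(log10(kd) - 1.5, log10(kd) + 1.5, length.out = 10)
    pts <- data.frame(dtot_corrected_uM = d,
                      percent_dimer = fraction_dimer(d, kd))
    hyp <- fit_kd_hyperbolic(pts)
    man <- fit_kd_manning(pts)
    expect_lt(abs(hyp$kd_uM / kd - 1), 1e-6)
    expect_lt(abs(hyp$kd_uM / man$kd_uM - 1), 1e-6)
  }
  expect_error(fit_kd_hyperbolic(data.frame(dtot_corrected_uM = 1,
                                            percent_dimer = 50)),
               "at least 4")
})

test_that("kd_fit methods expose estimate, predictions and diagnostics", {
  d <- 10^seq(-1, 2, length.out = 8)
  fit <- fit_kd_manning(data.frame(dtot_corrected_uM = d,
                                   percent_dimer = fraction_dimer(d, 1.2)))
  expect_equal(unname(coef(fit)["kd_uM"]), 1.2, tolerance = 1e-6)
  expect_equal(predict(fit, 1.2), 60.96, tolerance = 1e-2)
  s <- summary(fit)
  expect_s3_class(s, "summary.kd_fit")
  expect_output(print(fit), "Kd = 1.2")
})

test_that("free-slope Manning fit flags non-theoretical slopes", {
  d <- 10^seq(0, 2, length.out = 6)
  # points fabricated with slope 0.5 in the Manning plane
  y <- 0.5 * log10(d) - 1
  pd <- vapply(y, function(yy) {
    uniroot(function(x) manning_y(x) - yy, c(1e-6, 100 - 1e-6),
            tol = 1e-12)$root
  }, numeric(1))
  expect_warning(
    fit <- fit_kd_manning(data.frame(dtot_corrected_uM = d,
                                     percent_dimer = pd),
                          fix_slope = FALSE),
    "deviates")
  expect_equal(fit$slope_unconstrained, 0.5, tolerance = 1e-6)
})

test_that("equilibrium_points applies the per-injection dilution correction", {
  p <- sec_presets("ahb1_oxy")
  chroms <- simulate_sec_series(p, seed = 4)
  pts <- equilibrium_points(chroms, p$column)
  expect_equal(nrow(pts), 12)
  expect_true(all(pts$dtot_corrected_uM <= pts$dtot_loaded_uM))
  expect_equal(pts$dilution_factor, rep(8, 12), tolerance = 0.05)
  expect_equal(pts$dtot_corrected_uM, pts$dtot_loaded_uM / pts$dilution_factor)
  # a fixed global dilution factor can override the measured one
  pts_fix <- equilibrium_points(chroms, p$column, dilution_factor = 8)
  expect_equal(pts_fix$dtot_corrected_uM, pts_fix$dtot_loaded_uM / 8)
})

test_that("stochastic Kd recovery at 1% noise over 10 seeds", {
  for (nm in c("ahb1_oxy", "ahb1_ferric", "ahb1_t45a")) {
    p <- sec_presets(nm)
    err <- vapply(1:10, function(s) {
      fit <- suppressWarnings(
        fit_kd_sec(simulate_sec_series(p, s), p$column))
      abs(log10(fit$kd_uM / p$kd_uM))
    }, numeric(1))
    expect_lt(median(err), 0.1)
  }
})
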