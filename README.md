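# hemequil

Quantitative analysis of plant non-symbiotic hemoglobin self-association
and heme coordination.

Class-1 non-symbiotic hemoglobins (nsHbs) such as Arabidopsis AHb1 form
weak, concentration-dependent homodimers, and their heme iron equilibrates
between hexacoordinate (distal histidine bound) and pentacoordinate states.
Neither equilibrium is observable directly; both are inferred from indirect
measurements. This package implements the three estimation pipelines used
for that inference, for protein biophysicists analysing size-exclusion
chromatography (SEC) traces, native gels and visible absorbance spectra:

1. **Monomer-dimer Kd from SEC.** Under fast exchange a self-associating
   protein elutes as one peak between the monomer volume `Vm` and dimer
   volume `Vd`. The percent dimer follows
   `%D = 100 (2^((Vm - Ve)/(Vm - Vd)) - 1)`, and mass action with total
   concentration in dimer equivalents (`[Dtot] = [M]/2 + [D]`,
   `Kd = [M]^2/[D]`) gives `Kd = Dtot · 0.04 (100 - %D)^2 / %D`. The plot of
   `log10[%D / 0.04(100-%D)^2]` vs `log10 Dtot` is a line of slope 1 whose
   zero crossing is `Kd`. The pipeline measures each injection's dilution
   factor (peak FWHM / load volume) to correct loaded to on-column
   concentration, and offers both the slope-1 linearized estimator and a
   direct hyperbolic least-squares fit.
2. **Ferguson-plot mass estimation from native PAGE.** Retardation
   coefficients `Kr = -d[100 log10(100 Rf)]/d%T` per protein, a log-log
   standard curve of `Kr` vs molecular mass, and inversion for unknowns.
3. **Pentacoordinate fraction from deoxy visible spectra.** Either the
   classic A555/A540 band-ratio inversion against pure hexa/penta reference
   spectra, or a full-band two-endmember least-squares unmixing that is
   invariant to concentration and pathlength.

Supporting tools: CSV trace I/O, adjacent-averaging smoothing, SEC column
calibration, a two-state thermal-melt fit, and a fully seeded
synthetic-data generator (chromatograms, gel tables, spectra, melt curves)
with presets encoding the study conditions, so every estimator is validated
by ground-truth parameter recovery.

## Worked example

Simulate a 12-point SEC concentration series at the ferrous-oxy preset
(true Kd 1.2 uM, dilution factor 8, 1% peak noise) and recover the
dissociation constant:

```r
library(hemequil)

preset <- sec_presets("ahb1_oxy")
chroms <- simulate_sec_series(preset, seed = 42)
fit <- fit_kd_sec(chroms, preset$column)
summary(fit)
#> Kd = 1.229 uM (95% CI 1.098-1.375), manning estimator, n = 12
#> Unconstrained Manning slope: 1.020 (theory: 1)
```

The estimate (1.229 uM) recovers the generator's ground truth of 1.2 uM
within its confidence interval, and the unconstrained slope sits at the
theoretical value of 1, confirming two-state monomer-dimer behavior. Each
point's on-column concentration came from its own measured dilution factor:

```r
peak_metrics(chroms[[12]], smooth_window = 9)
#> Peak: apex 7.387 mL (height 85.06), FWHM 0.802 mL, dilution factor 8.02
```

Estimate the pentacoordinate fraction of a noisy synthetic deoxy spectrum
by spectral unmixing, and a monomer mass from noiseless Ferguson gels:

```r
refs <- make_reference_shapes()
spec <- simulate_deoxy_spectrum(0.65, noise_frac = 0.005, seed = 42)
penta_fraction_unmix(spec, refs)
#> Pentacoordinate fraction (unmix): f = 0.651 (65.1%)

std <- data.frame(
  protein_id = c("alpha_lactalbumin", "carbonic_anhydrase", "egg_albumin",
                 "bsa_monomer", "bsa_dimer"),
  mw_kda = c(14.2, 29, 45, 66, 132))
ferguson_analysis(simulate_gel_runs(std, unknown_mw_kda = 17.871), std)
#> Ferguson standard curve: log10 Kr = -0.3010 +0.7000 * log10 MW(kDa)  (R^2 = 1.0000)
#>   unknown: Kr = 3.762 -> 17.87 kDa
```

A command-line wrapper is installed at `exec/hemequil` inside the package
library (subcommands `simulate`, `calibrate`, `fit-kd`, `ferguson`,
`coordination`, `melt`, `presets`); the same interface is callable as
`hemequil_run()`.

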