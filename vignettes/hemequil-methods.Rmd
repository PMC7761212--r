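---
title: "Methods: monomer-dimer equilibria and heme coordination from SEC, native PAGE and visible spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monomer-dimer equilibria and heme coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemequil)
```

# The scientific problem

Class-1 non-symbiotic plant hemoglobins such as Arabidopsis AHb1 form weak,
concentration-dependent homodimers, and their heme iron sits in an
equilibrium between a hexacoordinate (distal histidine bound) and a
pentacoordinate (free ligand site) state. Both equilibria are functionally
important — the pentacoordinate fraction controls ligand binding — and both
are measured with low-information, indirect experiments: analytical
size-exclusion chromatography (SEC), native-PAGE Ferguson plots, and visible
absorbance spectra. This package implements those three estimation pipelines
plus the supporting primitives (trace I/O, smoothing, a two-state thermal
melt fit) and a seeded synthetic-data generator that produces ground-truth
inputs for every stage, so each estimator can be validated by parameter
recovery.

# Monomer-dimer Kd from SEC

## Model

A monomer-dimer system in fast exchange on the SEC timescale elutes as a
single peak whose position reflects the equilibrium-weighted species
mixture. With a log-linear column calibration, the elution volume of the
pure monomer ($V_m$) and pure dimer ($V_d$) bracket the observed volume
$V_e$, and the percent dimer follows

$$\%D = 100\left(2^{(V_m - V_e)/(V_m - V_d)} - 1\right),$$

equivalently the effective molecular mass is $\mathrm{MW} = A(1 + \%D/100)$
with $A$ the monomer mass. Total protein concentration is expressed in
*dimer equivalents*, $[D_{tot}] = [M]/2 + [D]$; mixing this convention with
monomeric units silently doubles the fitted $K_d$, so all interfaces take
dimer equivalents. Mass action with $K_d = [M]^2/[D]$ gives

$$K_d = [D_{tot}]\,\frac{0.04\,(100-\%D)^2}{\%D},$$

so a plot of $y = \log_{10}[\%D/(0.04(100-\%D)^2)]$ against
$\log_{10}[D_{tot}]$ is a straight line of slope 1 crossing $y=0$ exactly
where $[D_{tot}] = K_d$ (there $\%D \approx 61.0$). `fit_kd_manning()` fixes
the slope to 1 by default — the theory line — and always reports the
unconstrained OLS slope as a diagnostic, warning beyond $|m-1|>0.15$; a
free-slope fit is available because either reading of the original method is
defensible. `fit_kd_hyperbolic()` fits the same mass-action curve directly
in $\log_{10} K_d$ (a one-dimensional least-squares search bracketed by the
Manning estimate); on noiseless data the two agree to $10^{-6}$ relative,
and the pair provides an internal consistency check on real series.

`fraction_dimer()` evaluates the closed-form root of the quadratic in the
cancellation-free form
$\%D = 800 D_{tot} / [(8D_{tot}+K_d) + \sqrt{K_d(K_d+16D_{tot})}]$, which is
stable for $K_d \gg D_{tot}$; it is tested against an independent bisection
oracle.

## Dilution correction

The concentration loaded on the column is not the concentration at which
the equilibrium reports: the band dilutes during elution. Following
standard practice the dilution factor is the peak width at half height
divided by the injection volume, measured per injection from the trace
(`peak_metrics()`); a fixed global factor can be supplied instead. Points
with $\%D$ outside $[1, 99]$ carry almost no information about $K_d$ and are
excluded from the log transform with a warning; a series that sits entirely
(up to noise, $\%D < 2$) below the window is reported as
"no association detected" — the correct description of an obligate monomer
rather than a failed fit.

## Peak extraction choices

The apex is refined by a parabola through the three samples around the
maximum and the FWHM by linear interpolation of the half-maximum crossings,
after subtracting a baseline (median of the outer 5% of samples — real
traces carry small offsets). On a finely sampled trace the 3-point vertex is
exact for noiseless data but noise-dominated at realistic noise, so
`peak_metrics()` accepts an adjacent-averaging `smooth_window` (the same
primitive instrument software applies); the default is 1 (off), keeping the
analytic contracts exact, and the Kd pipeline (`equilibrium_points()`) uses
window 9, which at the generator's 0.01 mL sampling spans 0.09 mL — small
against the ~0.34 mL peak sigma, inflating FWHM by under 0.6% while cutting
apex noise roughly three-fold. Tied maxima resolve to the leftmost with a
warning; a maximum at a trace end or a second substantive region above the
half line is an error (`"truncated peak"`, `"multi-peak trace"`). Runs of
fewer than 3 samples above the half line are treated as noise blips, not
peaks.

## Column calibration

`fit_sec_calibration()` regresses $\log_{10}\mathrm{MW}$ on raw elution
volume, as is conventional for a single-column analysis; a partition
coefficient ($K_{av}$) parameterisation would need the void and total
volumes, which are rarely reported, and cancels out of the monomer/dimer
endpoint logic anyway. The synthetic column geometry — $V_m = 8.719$ mL,
$V_d = 7.214$ mL on the line $\log_{10}\mathrm{MW} = 3.0 - 0.2\,V_e$ — was
chosen once so that the endpoints correspond exactly to the AHb1 monomer
(18.034 kDa) and dimer (36.068 kDa) masses; real column volumes are
instrument-specific and all of this is configurable via `column_model()`.

# Ferguson analysis of native PAGE

Electrophoretic mobility on a native gel falls off log-linearly with gel
concentration, $\log_{10} R_f$ linear in $\%T$, at a rate (the retardation
coefficient $K_r$) set by molecular size. `retardation_coefficient()` fits
$100\log_{10}(100 R_f)$ against $\%T$ and returns $K_r = -\text{slope}$;
`fit_ferguson_standard_curve()` fits $\log_{10} K_r$ against
$\log_{10}\mathrm{MW}$ over the standards, and `estimate_mw_ferguson()`
inverts that power law for an unknown. All logs are base 10; any fixed base
cancels in the round trip. Non-sieving species ($K_r \le 0$) are flagged and
excluded from the standard curve. The simulator generates $R_f$ directly
under ideal Ferguson behavior ($R_f = 0.9 \cdot 10^{-K_r \%T/100}$,
$K_r = 0.5\,\mathrm{MW}^{0.7}$) — densitometry of gel images is out of
scope, and real gels add band-shape and gel-to-gel variation this model
deliberately omits.

# Pentacoordinate fraction from deoxy spectra

The deoxy visible spectrum of these proteins is a two-species mixture. The
hexacoordinate endmember has resolved alpha/beta bands (near 557/527 nm)
with a trough near 540 nm; the pentacoordinate endmember is one broad band
near 558 nm. Two estimators are provided because the original single-number
indicator — the A555/A540 ratio — does not fully determine the inversion:

- `penta_fraction_from_ratio()` solves the mixture ratio
  $r = \frac{f P_{555} + (1-f) H_{555}}{f P_{540} + (1-f) H_{540}}$ for $f$.
  The ratio of a mixture is a *rational* function of $f$, so the inversion
  uses the references' absolute post-normalization values at both
  wavelengths, not just their ratios.
- `penta_fraction_unmix()` is a full-band least-squares decomposition
  $A(\lambda) \approx c[f P(\lambda) + (1-f) H(\lambda)]$ over a window
  (default 500-600 nm) with the free scale $c$ absorbing concentration and
  pathlength — the estimate is exactly invariant to rescaling the input.
  Negative component amplitudes clamp to the nearer boundary ($f=0$ or 1).

References are area-normalized over 450-650 nm by default
(`reference_pair()`): the mixture model needs commensurate endmembers, and
unit area is the convention that survives unknown concentrations. No
baseline term is included by default; measured spectra should be
blank-subtracted first. Because the ratio estimator reads two single
wavelengths it is markedly noisier than the full-band unmixing; the built-in
reference shapes (`make_reference_shapes()`) were designed with a genuine
540 nm trough (endmember ratios ~3.4 vs ~1.4) so that both estimators are
well conditioned. The shapes are synthetic, deterministic and
area-normalized; they emulate plausible band structure, not measured
spectra.

# Two-state thermal melt

`fit_two_state_melt()` fits the minimal standard model — a two-state
sigmoid $\sigma(T) = 1/(1+e^{(T_m-T)/w})$ between linear folded and unfolded
baselines — by nonlinear least squares. The functional form is this
package's documented assumption; melting temperatures are often reported
without one. Initialisation: $T_m$ at the steepest signal change, $w = 2$
°C, baselines from the outer 10% of points; $T_m$ is constrained inside the
observed range. A fit whose transition amplitude is small against the
signal excursion or the noise, or whose $T_m$ pins to the range boundary, is
rejected as "no transition detected".

# The synthetic-data generator

Every generator is a pure function of its arguments including the seed; a
master seed spawns deterministic per-item streams, and the noiseless part of
each simulation is independent of the seed. The presets encode the study
conditions:

| preset | truth | series | dilution | noise |
|---|---|---|---|---|
| `ahb1_oxy` | $K_d$ = 1.2 uM | 0.07-85 uM, 12 pts | 8 | 1% of peak |
| `ahb1_ferric` | $K_d$ = 11 uM | 0.1-300 uM, 12 pts | 8 | 1% |
| `ahb1_t45a` | $K_d$ = 876 uM | 1-1000 uM, 12 pts | 7 | 1% |
| `ahb2` | obligate monomer (17.871 kDa) | 0.1-60 uM, 12 pts | 6 | 1% |
| `wild_type` (coordination) | f: 13% @ 1 uM to 65% @ 190 uM | log-interpolated | — | 0.5% |
| `t45a` (coordination) | f = 26%, 0.7-350 uM | flat | — | 0.5% |

The ferrous-oxy and monomer concentration ranges are the reported ones; the
ferric and T45A ranges were chosen once to bracket each $K_d$ the same way
the reported range brackets the ferrous-oxy value. Chromatograms sample
0.01 mL steps over $[V_d - 1.6, V_m + 1.6]$ mL (about 470 points, ~80 per
peak FWHM), Gaussian peaks with FWHM = dilution x load volume and height
proportional to load, additive noise relative to height. Coordination
presets interpolate $f$ linearly in $\log_{10}$ concentration between their
anchors. Melt curves sample 20-100 °C at 0.25 °C.

What the generator does *not* emulate — and what recovery tests therefore do
not show about real data: column non-ideality (the real monomer's apparent
SEC mass exceeds its true mass; deliberately not reproduced), tailing or
asymmetric peaks, slow-exchange two-peak regimes, gel-to-gel Ferguson
variation, spectral baselines and stray light, and any higher-order
oligomers.

# Numerical choices and degenerate inputs

- `fraction_dimer` uses the conjugate closed form (no cancellation for
  $K_d \gg D_{tot}$); $K_d = 0$ returns exactly 100.
- The elution/\%D maps are exact inverses to $10^{-10}$ over $[0, 100]$.
- \%D outside $[V_d, V_m]$ clips to $[0, 100]$ with a warning rather than
  erroring: noisy apexes legitimately stray just past an endpoint.
- Out-of-order trace rows sort with a warning; duplicated abscissae are an
  error. Parse errors name the offending line.
- Adjacent averaging: odd windows centered, even windows trailing (point
  and predecessors) to match common instrument behavior; edges truncate;
  output length equals input length.
- The hyperbolic fit's standard error comes from the curvature of the RSS
  profile in $\log_{10} K_d$.

# Problem sizes

The validation suite runs recovery at the preset study conditions: 10
simulated 12-point SEC series per Kd preset, 20 spectra per coordination
anchor, 20 noisy gel tables, and melt fits over four $T_m$ values — sizes at
which each stochastic check stabilises well below its tolerance while the
whole suite stays interactive.

# Limitations

The Kd estimators assume a single fast-exchange peak and a two-state
monomer-dimer system; they will silently mis-estimate mixed or higher-order
systems (the multi-peak guard catches only resolved extra peaks). The
coordination estimators assume the measured spectrum is a nonnegative
combination of exactly the two supplied references with no baseline. The
melt fit reports a $T_m$ conditional on the two-state model; calorimetric
enthalpies are out of scope.
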