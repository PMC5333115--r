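---
title: "Models and methods: ee and conversion from online HPLC-ECD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ee and conversion from online HPLC-ECD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiroptic)
```

# The measurement model

A dual UV/ECD detector records, at one wavelength (250 nm by default),
ordinary absorbance A in mAU and ellipticity θ in mdeg on the same time
grid. The package's working model for a chiral product eluting with both
enantiomers present is

- UV channel: response proportional to the total concentration
  `c_R + c_S`,
- ECD channel: response proportional to the signed difference
  `c_R − c_S`, with the proportionality fixed by the pure enantiomer's
  dissymmetry factor `g_pure`.

The Kuhn dissymmetry factor is the ratio of the circular-dichroic
absorbance difference to the absorbance, computed here from integrated
peak areas:

$$ g = \frac{\Delta A}{A}, \qquad
   \Delta A = \frac{\theta\,[\mathrm{mdeg}]}{32980}, \qquad
   A = \frac{\mathrm{mAU}}{1000}. $$

Both areas scale with the amount injected, so the concentration cancels:
for a fixed composition, g is a property of the mixture alone, and

$$ g_{\mathrm{mix}} = ee \cdot g_{\mathrm{pure}}, \qquad
   ee = \frac{c_R - c_S}{c_R + c_S} \in [-1, 1]. $$

`estimate_ee()` is exactly this ratio. The sign convention follows the
reference enantiomer used for `g_pure` (R by default): positive ee means
R excess. Because only the *ratio* of two g values enters, the two unit
constants (32980 mdeg per ΔA, 1000 mAU per AU) cancel in the ee; they are
exposed as arguments of `compute_g_factor()` anyway so the g values
themselves are on the conventional ΔA/A scale. No numeric g value is
asserted against external data anywhere — only ratios and signs carry
scientific weight here.

The conversion ratio is area-percent at the detection wavelength,

$$ CR = 100 \cdot \frac{P/r}{P/r + S}, $$

with P and S the product and substrate UV areas and r a product-to-
substrate response factor. Substrate and product generally absorb
differently at a fixed wavelength; with no measured molar-absorptivity
ratio available, the default is r = 1 and the parameter is exposed in
`conversion_ratio()` and `pipeline_config()`. This is the one deliberate
approximation of the conversion stage.

## Decision rules and degenerate inputs

- `|ee|` slightly above 1 (up to 1.05) is clipped to 1 with a warning —
  detector noise on a nearly pure sample legitimately lands there;
  beyond 1.05 the reference g is considered inconsistent and the call
  errors.
- A sample is called *racemic* when `|ee|` falls below `racemic_floor`
  (default 0.005, i.e. 0.5 % ee, below plausible detector precision).
- A zero or negative UV area is a degenerate input (no analyte), an
  error rather than a NaN.
- In calibration fits, a zero-variance response makes r² undefined; the
  fit reports `r_squared_defined = FALSE` instead of forcing 0 or 1.
- The concentration-invariance check uses the population CV,
  `sd_pop/|mean|`, and refuses racemic series (mean g ≈ 0) where a CV is
  meaningless.

# Peak detection and integration

Apexes are local maxima of the baseline-corrected UV trace — optionally
smoothed with a centred moving average (`smoothing_window`, default 1 =
off) — that exceed `min_height` and a topographic-prominence threshold
`min_prominence`. Peak bounds walk outward from the apex to the nearest
point where the smoothed corrected signal falls to `bound_frac` of the
apex height (default 0.001, i.e. ±3.7σ on a Gaussian, covering 99.98 % of
its area), stopping early at the valley shared with a neighbouring peak.

Areas are always trapezoid integrals of the **unsmoothed** traces over
those bounds, after baseline subtraction; smoothing only stabilises apex
localisation under noise. Two baseline models are provided:

- `linear-endpoints` (default): a straight line through the window
  endpoints, appropriate for locally flat or linearly drifting
  baselines;
- `rolling-minimum`: a morphological opening (rolling minimum followed by
  rolling maximum, window `rolling_width` points) for curved drifts. The
  opening carries a small positive bias where the baseline slopes under a
  peak — the erosion minimum is then contaminated by the peak flank — so
  integrated areas are accurate to a few percent under strong curvature;
  the tests pin this at 5 %.

The ECD channel is integrated over the *UV-determined* bounds: the two
detectors see the same eluate, and the ECD trace of a near-racemic sample
can cross zero inside the peak, so bounds derived from the ECD channel
itself would be ill-defined. The trapezoid rule on the raw grid (via
`pracma::trapz`) keeps integration deterministic and testable against
closed forms: a synthetic Gaussian of amplitude A and width σ_t matches
A·σ_t·√(2π) to ~0.3 % at the default settings. Retention-time accuracy is
one grid step.

The height/area question is settled in favour of areas for all
quantitation: areas are robust to band broadening, and the generator's
ground truth is written in area terms.

# ECD spectrum simulation and configuration assignment

Transition tables (per conformer: excitation energies in eV, rotational
strengths in 10⁻⁴⁰ cgs, relative energies in kcal/mol) are convolved with
Gaussian bands in energy space:

$$ \Delta\varepsilon(E) =
   \frac{1}{2.297\times10^{-39}\,\sqrt{\pi}\,\sigma}
   \sum_i E_i\, R_i\, e^{-\left((E - E_i)/\sigma\right)^2}, $$

with σ = 0.35 eV by default, interpreted as the width parameter of the
exponent exactly as written (not a FWHM). The prefactor is the standard
Δε band-shape convention with E·R weighting; the absolute-configuration
call depends only on the **sign** of Δε at the probe wavelength, which is
convention-independent, so the prefactor choice cannot change an R/S
assignment. Conformers are combined with Boltzmann weights
`exp(−ΔE/kT)/Σexp(−ΔE/kT)`, kT in kcal/mol (k = 0.0019872), at 298.15 K
by default. Which electronic energies (SCF vs free) and which temperature
best represent a given ensemble is left to the caller — both are plain
inputs. Energy and wavelength interconvert via `E = 1239.842/λ`.

The spectrum is evaluated pointwise on the wavelength grid — the formula
is not discretised — so refining the grid never changes values at common
points, and a single-transition band integrates (over E) to
`E_i·R_i·10⁻⁴⁰ / 2.297×10⁻³⁹` to better than 0.5 % on a ±5σ grid; both
are regression-tested. `assign_configuration()` refuses to call a
configuration when the simulated spectrum at the probe wavelength is
below a significance floor (default 0.01 L mol⁻¹ cm⁻¹): near a node, a
sign comparison is meaningless and another wavelength must be chosen.

# Orthogonal-array range analysis

`build_L9()` returns the standard L9(3⁴) array (each level three times
per column; every ordered level pair exactly once per column pair). Three
columns carry catalyst loading (5/10/20 mol %), temperature (−10/0/10 °C)
and time (8/16/24 h); the fourth is kept internally as the error column
and excluded from reports.

Range analysis computes, per factor and level, the mean M of the response
over the three matching runs, and per factor the range
R = max(M) − min(M). All arithmetic is full precision; **display**
rounding is half-up to two decimals, and R is always computed from
unrounded means (rounding first would, e.g., turn the conversion-ratio
range for temperature from 1.98 into 1.97). Larger responses are treated
as better for both conversion and optical purity. Ties in R preserve
factor declaration order and ties in M pick the lowest level, both
flagged in the result. The balanced design implies a conservation law —
the mean of the three level means equals the grand mean — which is
asserted to 1e-9 in the tests as a structural invariant.

The packaged 9-run screening table (conversion ratio and optical purity
of the hydrosilylation product) is instrument-derived input, shipped as a
fixture; "optical purity" is reported as ee % of the dominant enantiomer.
The printed reference summary for that table rounds a few second decimals
inconsistently (e.g. a level mean printed 99.73 where full precision
gives 99.7233), so reproduction tests use a ±0.02 band for all cells and
exact round-half-up equality for the arithmetically stable ones.

# The synthetic-data generator

`gen_chromatogram()` emulates the two measurement regimes: on the achiral
column both enantiomers co-elute in one product peak; on the chiral
column they resolve (defaults near 23.78 and 28.71 min, mirroring typical
observations — defaults, not predictions). Species traces are unit-area
Gaussians (or exponentially modified Gaussians for tailing, `tau > 0`)
scaled by `concentration × uv_response`, so peak area — not height —
carries amount, as in a real absorbance detector. The ECD trace is the
product shape scaled by `(c_R − c_S)·uv_response·g_pure·32.98`, which
makes the generator/analyzer round trip exact by construction in the
noise-free limit: `compute_g_factor` over the product peak returns
`g_pure·(2 f_R − 1)`. The substrate is modelled ECD-silent (an achiral
enamine).

Noise is multiplicative per point and per channel (`noise_sd_rel`), plus
an optional linear UV baseline drift in mAU/min — two parameters that
capture the dominant instrument behaviours. Consequences worth knowing:
a racemate's ECD trace is exactly zero under purely multiplicative noise,
so the racemate-null tests probe the cancellation `c_R = c_S`, not
additive detector noise; and drift is applied to the UV channel only (the
ECD channel of a dual detector is typically flat). `g_pure` defaults to
1e-3, typical of allowed electronic transitions of organic chromophores;
`uv_response` defaults to 100 mAU per concentration unit. All generators
are deterministic under a seed and restore the caller's RNG state.

What the generator does **not** emulate: retention modelling from column
chemistry, gradient elution, detector saturation, wavelength-dependent
response, additive (signal-independent) noise, and co-elution of
substrate with product. Passing tests therefore demonstrate the
*statistical machinery* — concentration cancellation, linearity, ee
recovery under proportional noise, factor-effect recovery — not the
behaviour of any physical column.

`gen_transition_table()` draws conformer energies uniformly on
[0, 3] kcal/mol (minimum forced to zero) and rotational strengths from a
centred normal; its only scientific claims are structural (one zero-energy
conformer, positive excitation energies, exact mirror symmetry under
negation). `gen_oa_responses()` builds responses from an additive
factor-effect model, under which range analysis provably recovers each
factor's effect span and argmax level exactly at zero noise.

# Problem sizes and reproducibility

The stochastic study used by the tests and the acceptance script runs the
composition grid f_R ∈ {0, 0.1, …, 1} with 50 seeded replicates each at
1 % multiplicative noise (550 chromatograms of ~760 points; a few seconds
of compute), chosen to estimate the mean absolute ee error stably while
keeping the whole suite fast. Concentration invariance uses four
noise-free injections spanning 10× (0.2–2 concentration units). Every
random draw flows from an explicit seed; identical seeds give identical
chromatograms, tables and reports, and reports contain no timestamps.

# Known limitations

- The conversion ratio is only as good as the response factor; r = 1 is
  a stated approximation, not a calibration.
- ee accuracy degrades near the racemic point in *relative* terms (g → 0
  while its absolute noise floor is set by the UV area), though the
  absolute ee error stays small.
- The rolling-minimum baseline biases areas low by a few percent under
  strongly sloping baselines (opening overshoot); prefer
  linear-endpoints whenever drift is locally linear.
- Overlapping peaks are split at the shared valley rather than
  deconvolved; quantitation of heavily fused peaks is out of scope.
- The ECD band-shape prefactor and Boltzmann-averaging choices are
  conventions; any quantity that depends on them beyond sign (absolute
  Δε magnitudes) should be read as convention-relative.
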