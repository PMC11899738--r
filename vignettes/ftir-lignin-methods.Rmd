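---
title: "Relative lignin quantification from ATR-FTIR spectra: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative lignin quantification from ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirlignin)
```

## The problem

Lignin content in plant biomass is classically measured by destructive wet
chemistry. Mid-infrared (ATR-FTIR) spectroscopy offers a fast, non-destructive
alternative: aromatic skeletal vibrations of lignin produce characteristic
bands in the fingerprint region (~800–1800 cm⁻¹), and after suitable
pretreatment their second-derivative peak heights track lignin content.
`ftirlignin` implements a complete relative-quantification workflow:

1. **Pretreatment**: replicate averaging → basic ATR correction → unit vector
   normalization (UVN) → Savitzky–Golay (SG) second derivative (15 points,
   2nd order) → extended multiplicative scatter correction (EMSC), windowed
   to the fingerprint region.
2. **Calibration**: second-derivative peaks that appear in a pure-lignin
   standard, are absent from pure cellulose, and are matched in plant
   spectra are regressed (peak height vs known lignin weight fraction) over
   a binary lignin/cellulose mixture series; peaks pass a
   Pearson *r* ≥ 0.75, *p* < 0.05 gate.
3. **Quantification**: for each selected peak the exposed/control relative
   change is `100·(mean exposed height / mean control height − 1)`, tested
   by a tiered scheme (normality → variance homogeneity → Student/Welch/
   Kruskal–Wallis).
4. Satellite stages: a four-parameter logistic (4PL) dose–response fit with
   bootstrap EC50 uncertainty, and hypergeometric GO fold-enrichment
   arithmetic with a Bonferroni gate.

Because no public spectra accompany this class of experiment, a first-class
synthetic-data module generates every input with known ground truth.

## Pretreatment: definitions and numerical choices

**ATR correction.** ATR absorbance carries an effective-path-length weighting
proportional to 1/ν̃. The "basic" correction multiplies each point by
ν̃/ν̃₀ with ν̃₀ = 2000 cm⁻¹, which leaves the value at the anchor unchanged.
It is deliberately minimal and can be disabled (`atr_reference = NA`).

**UVN.** Each spectrum is scaled to unit Euclidean norm *over the working
window only*, so that normalization never depends on discarded spectral
regions.

**SG second derivative.** A local quadratic least-squares fit in a sliding
15-point window; the filter is exact on polynomials of degree ≤ 2, linear,
and its `(w−1)/2` edge points are marked invalid and excluded from all peak
work. Values are scaled by 1/spacing² so units follow the wavenumber axis.
Non-uniform grids are rejected; `resample_spectra()` must be called
explicitly, because silent interpolation would corrupt the derivative scale.

**EMSC.** Each spectrum `x` is decomposed against the set's pointwise mean
`ref` as `x = a + b·ref + Σ d_k p_k(ν̃) + e` (orthogonal polynomials up to
order 2) and replaced by `ref + e/b`. Spectra with `|b| < 1e−6` are rejected
as unrelated to the reference. The chain applies EMSC **after** the second
derivative — the literal listed order of the emulated workflow —
with `emsc_on = "absorbance"` available for the conventional pre-derivative
placement. Both orders lead to the same projective structure discussed next.

### The projective-normalization algebra (why the defaults look the way they do)

UVN divides a spectrum by its norm; EMSC later divides the residual by the
regression coefficient `b`, which is itself proportional to that same norm.
The two cancel: writing a noiseless spectrum in band space as
`x = p·L + q·C` (lignin and cellulose shapes `L`, `C`), the processed
output is

```
corrected = ref + (p·M L + q·M C) / (p·U + q·V)
```

with `M` a fixed linear projector and `U, V` scalars formed from the set
mean. Three consequences drive the package's design:

* **Per-spectrum scale invariance is exact — given a fixed reference.** Any
  affine distortion `a + m·x` of one spectrum cancels completely, *provided*
  `ref` is held fixed. With the default set-mean reference, the reference
  itself shifts when individual spectra are rescaled, leaving a residual of
  order 10⁻³–10⁻². `emsc_correct(reference = …)` therefore supports the
  standard calibrate-then-predict workflow, and the test suite asserts
  exact invariance (≤ 10⁻⁶) in that mode.
* **Standard curves are exactly linear iff `U = V`.** For a mixture series
  with symmetric fractions this reduces to: the pure lignin and cellulose
  profiles must carry equal norms in absorbance space *and* in
  second-derivative space. The default generator profiles are numerically
  balanced to satisfy this (`default_profiles()` solves for the cellulose
  band width and amplitude), so noiseless standard curves reach
  Pearson r = 1 to ~10⁻¹² — and, importantly, the *method's* selection gate
  (r ≥ 0.75) is robust far from this idealization.
* **The cohort ratio estimator has a small composition-dependent bias.**
  For a cohort centred at control fraction `f_c` the estimator of a planted
  change δ converges to `(1+δ)·(f_c k + 1 − f_c)/(f_e k + 1 − f_e)` with
  `k ≈ f̄/(1−f̄)` under balanced profiles. At the defaults
  (`f_c = 0.12`, δ = +25 %) this evaluates to ≈ +28.7 % noiseless, and
  window-minimum noise bias pulls it back toward ≈ +22 % at the default
  noise level. The estimator is therefore validated as *relative signature
  change within a ±5-point band*, not as an unbiased fraction estimator.

## The synthetic world

The generator emulates:

* **Standards**: 13 binary lignin/cellulose mixtures, fractions evenly
  spaced on [0, 1] (the bench design's exact ratios are not published; even
  spacing is an assumption).
* **Cohort**: 16 exposed vs 33 control plants, 3 scans each. Control lignin
  fraction 0.12 (a realistic Klason-lignin share of young whole-plant
  tissue), default planted change +25 %, between-plant fraction sd 0.015.
* **Bands**: lignin doublets at 1417/1423, 1464/1472, 1515/1521,
  1617/1623 cm⁻¹ (σ = 3 cm⁻¹; 1515 strongest), cellulose bands at
  898–1370 cm⁻¹ with width and amplitude set by the norm balance above.
* **Distortions**: lognormal multiplicative scatter (sdlog 0.1), quadratic
  additive baseline, iid Gaussian noise (sd 0.01 ≈ 1 % of the strongest
  band), and the deterministic 1/ν̃ ATR weighting — exactly the effects the
  pretreatment chain claims to remove, so the chain is falsifiable.
* **Grid**: 800–1800 cm⁻¹ at 0.5 cm⁻¹. A 4 cm⁻¹-resolution instrument with
  standard zero-filling produces ≈0.5 cm⁻¹ point spacing; at 2 cm⁻¹ spacing
  the 15-point SG kernel would span 28 cm⁻¹ and provably cannot resolve the
  6 cm⁻¹ doublets, so the finer spacing is the only self-consistent reading
  of the emulated workflow.

What the generator does **not** emulate: real plant matrices (hemicellulose,
protein, water bands), instrument drift, ATR contact variability, Mie-type
scattering, or any spectrum of the stressor compound itself. A green test
establishes that the pipeline recovers what this two-component world plants;
it does not establish accuracy on real tissue.

## Calibration and selection

Peaks are detected as local minima of the second derivative above a
prominence floor (fraction of the global maximum magnitude), with sub-grid
centers from a 3-point parabola. Lignin-specificity requires presence in
pure lignin, absence (within 4 cm⁻¹, the instrument resolution) from pure
cellulose, and a sample-side match. The cellulose *veto* uses a higher
floor (0.10) than the lignin side (0.05): genuine cellulose bands sit at
≥ 40 % of the maximum magnitude while 1 %-noise minima reach ~5 %, and a
low veto floor would let noise disqualify true lignin bands. Peak height is
the negated window minimum clipped at zero, so informative peaks correlate
*positively* with lignin content and the one-sided r ≥ 0.75 gate is
coherent. The Pearson p-value uses the exact t transform on n − 2 degrees
of freedom (n = 13 standards is small). Candidate and selected counts are
emergent — no wavenumber is hard-coded in the analysis path.

## Tiered group testing

Per peak and group, Shapiro–Wilk and a Lilliefors-corrected
Kolmogorov–Smirnov test (Monte-Carlo null with 10⁴ draws, cached per sample
size; plain KS with estimated parameters is anticonservative) assess
normality. If either test rejects in either group the comparison uses
Kruskal–Wallis; otherwise classic (mean-centred) Levene routes to the
pooled-variance Student or the Welch t-test, two-sided. No multiple-testing
correction is applied across peaks by default, matching per-peak 95 %
reporting; a Bonferroni switch exists. Zero-variance groups fall through to
the rank path rather than erroring.

## Dose–response stage

The 4PL "inhibitor vs response, variable slope" model
`y = bottom + (top − bottom)/(1 + (x/EC50)^hill)` is fit by multi-start
BFGS in `(bottom, top, log EC50, hill)` — EC50 starts at three log-dose
quantiles, the Hill slope tries both signs — followed by a Gauss–Newton
polish (`nls`, port, `scaleOffset = 1` so zero-residual round-trips
converge). Parameterizing in log EC50 with quantile-based starts makes the
fit exactly equivariant under dose rescaling. EC50 uncertainty is the
half-width of the central 68 % interval of case-resampling bootstrap
replicates; the plain bootstrap sd is inflated by occasional divergent
refits (resamples that lose the high doses) and overcovers badly, while the
percentile form is calibrated in simulation. Dose 0 anchors the `top`
asymptote (`bottom` for negative slopes).

## Enrichment arithmetic

DEG gates are strict by default (`fold change > 2`, `< 0.5`, adjusted
p < 0.05; a non-strict switch covers the `≥` reading). Fold enrichment is
`observed / (size · DEGs / universe)`; the significance test is the
hypergeometric upper tail (the default of PANTHER-class tools — the
emulated workflow names no test), Bonferroni-adjusted across listed terms,
gated at enrichment ≥ 1.5 and adjusted p < 0.05. Depleted categories get
the lower-tail probability. The gene universe is a required input; a helper
recovers it from any reported row as `size · DEGs / expected`.

## Known limitations

* Relative change only; no absolute lignin mass fraction, no S/G
  composition.
* The ratio estimator's projective bias (above) means planted and estimated
  change agree to a few points, not exactly, even noiselessly.
* The two-component synthetic matrix is far simpler than real biomass; the
  correlation gate's false-positive behaviour on rich matrices is untested.
* EMSC with the default set-mean reference makes results (slightly)
  set-dependent; fix the reference for transferable models.
* The Lilliefors null table is seeded internally for determinism; its p
  resolution is 1/(10⁴+1).
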