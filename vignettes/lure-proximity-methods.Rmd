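---
title: "Quantifying lure-flower proximity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lure-flower proximity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lureprox)
```

`lureprox` quantifies two axes of closeness between a deceptive spider lure
and neighbouring flowers — perceptual (colour) distance in a fly's visual
space and physical distance in cm — and models their joint effect on hourly
prey-interception rates. This vignette documents the science behind each
stage, the tunable parameters, and the choices made where the methodology
left genuine latitude.

## Spectral processing

Raw reflectance spectra (proportion reflected per wavelength, 300–700 nm)
arrive noisy, occasionally slightly negative near dark regions, and in
replicate. The pipeline is, in order:

1. **Resampling** (`resample_spectra()`): linear interpolation onto a 1-nm
   grid over 300–700 nm. One nanometre is the de-facto standard for
   reflectance work and makes downstream integration error negligible (the
   grid-refinement tests show catches move by well under 0.1% when the step
   is halved). Extrapolation beyond the measured range is refused rather
   than guessed.
2. **Smoothing** (`smooth_spectra()`): locally weighted regression with
   span 0.15. Only the span is a substantive choice; degree, weights and
   robustness iterations default to the canonical local-regression
   settings — locally quadratic, tricube weights, no robustness
   iterations — which is what the standard spectral-processing toolchains
   use. The span is the fraction of points in each local window; with 401
   grid points that is a ~60-point window, light enough to keep real
   spectral structure. A span leaving fewer than the three points a
   quadratic needs is a parameter error.
3. **Clamping** (`zero_negatives()`): instrument noise is zeroed pointwise
   (`max(r, 0)`), after smoothing and before averaging, matching the order
   in which field spectra are conventionally cleaned. Clamping is
   idempotent.
4. **Averaging** (`average_spectra()`): pointwise arithmetic mean of
   replicate measurements on an identical grid; mismatched grids are an
   error, not silently interpolated.

## The fly visual model

Dipteran prey dominate interceptions in this system, so colour similarity
is computed in a fly colourspace. The model uses all four chromatic
photoreceptor classes of the fly retina — the R7/R8 pairs of pale (p) and
yellow (y) ommatidia — at receptor level only:

* **Quantum catch**: `Q_i = ∫ R(λ) I(λ) S_i(λ) dλ`, composite trapezoid
  rule on the working grid, D65 daylight illuminant.
* **Relative catch**: `q_i = Q_i / Σ_j Q_j`. This removes overall
  intensity, so any positive scaling of the stimulus or illuminant leaves
  loci unchanged (tested to 1e-12). A stimulus with zero total catch has no
  locus; the package flags it rather than returning 0/0.
* **Opponent locus**: `x = q_R7p − q_R8p`, `y = q_R7y − q_R8y`, confining
  loci to `[−1, 1]²`.
* **Colour distance**: the Euclidean distance between loci — a continuous
  similarity measure, deliberately *not* the original categorical reading
  of this colourspace, and not a receptor-noise (JND) model. No chromatic
  adaptation (von Kries) step is applied: the model is receptor-level
  catches and opponent differencing, nothing downstream.

**Receptor curves.** Measured in vivo fly sensitivities incorporate
screening and sensitising pigments that shift peaks relative to the
underlying rhodopsins. The package does not bundle a digitised measured
dataset; instead it generates curves from the Govardovskii A1 visual
pigment template at the documented *Drosophila* rhodopsin peaks (Rh3 331,
Rh4 355, Rh5 442, Rh6 515 nm), and the bundled CSV asset
(`receptors_drosophila_synthetic.csv`) is exactly that template output —
labelled synthetic for that reason. `fly_receptors()` accepts arbitrary
`lambda_max`, so users with measured tabulations can substitute them; all
package tests run off the template so nothing depends on the asset.
Consequently absolute colour-distance values here are not numerically
identical to ones computed with measured sensitivities, though the
structure (matched ≪ mismatched) is robust to the choice.

## Field records

* Interception rate = total new prey / observed hours, from 30-min checks.
  Where sessions differ in length the per-individual duration is used
  rather than a nominal constant.
* The distance exclusion reads "over five metres" literally: records at
  exactly 500 cm are retained, `> 500` removed.
* Treatment levels for the factorial experiment are the 5th and 95th
  type-7 (linear interpolation) percentiles of the observed distances,
  rounded to whole cm. Type 7 is the default convention of R's
  `quantile()` and therefore of the surrounding analysis ecosystem.

## Inference

Both analyses are Gaussian identity-link GLMs (ordinary least squares).
Rates are continuous and can in principle be fitted below zero; no
truncation is applied, keeping the model well specified.

**Model selection.** The observational global model is
`rate ~ physical * (colour + colour² + colour³)`. `all_subsets()` fits
every subset respecting marginality — polynomial hierarchy among the colour
main effects (colour³ requires colour², which requires colour) and
interactions requiring both parents — which yields 19 candidates, verified
in the tests by an independent brute-force enumeration. AICc is
`−2·logLik + 2k + 2k(k+1)/(n−k−1)` with the Gaussian likelihood at its ML
variance and `k` counting that variance, the convention of the standard
information-theoretic model-selection toolchain. Ties in AICc are broken by
fewer parameters, then term order. Akaike weights renormalise
`exp(−Δ/2)`.

Polynomial terms use raw powers of colour distance by default (an
orthogonal basis is available via `poly_basis = "orthogonal"`). Because
colour distances occupy roughly `[0, 0.5]`, the powers — and hence the
interaction terms built from them — are strongly collinear. One practical
consequence, visible in the simulation tests: even under a strong generated
`physical × colour` interaction, near-neighbour models substituting
`physical:colour²` can win the AICc ranking for individual datasets, and
winning weights stay modest. The selection tests therefore assert that the
winner always carries the interactive structure, and that the generating
model is selected decisively within its own five-model family.

An option `standardize = TRUE` z-scores both predictors before fitting, for
comparison with analyses conducted on standardised scales; the default is
raw cm and raw colour distance.

**Conditional slopes.** For the leading model, the colour-distance slope at
physical distance d is `β_c + β_int·d` with variance
`Var(β_c) + d²Var(β_int) + 2d·Cov`, CI from the residual-df t quantile.
Tests verify the delta-method SE against a 10,000-draw parametric
bootstrap (2% tolerance) and that CI width is minimised at
`d* = −Cov/Var(β_int)`.

**Factorial analysis.** Treatment coding with reference cell
(far, matched), so the coefficients read as the near effect, the mismatch
effect and their interaction. Marginal means come from `emmeans`; in the
balanced design they equal raw cell means exactly. Pairwise contrasts use
the Tukey studentised-range adjustment — the standard choice for all-pairs
comparisons of a factorial's cells — and the compact letter display is
computed by the insert-and-absorb algorithm (`letter_display()`), written
in-package and checked against the property that adjusted p ≥ unadjusted p
and that an overwhelmingly shifted cell earns a unique letter.

## What the synthetic generators emulate

`sim_config(seed)` fixes everything; randomness flows through fixed
per-stage substreams (spectra, flower draws, web placement, capture noise),
so partial pipelines are independently reproducible.

* **Spider spectra**: yellow morphs are low below ~500 nm rising
  sigmoidally to a 0.5–0.7 plateau; white morphs broadly reflective
  (0.2–0.75) across the grid. Both are clipped to [0, 1] and carry optional
  measurement noise.
* **Flower spectra**: a sigmoid-plus-Gaussian-peak family spanning a wide
  range of fly-space loci; `target =` tunes parameters by coarse-then-fine
  grid search until the flower sits within `tol` (default 0.02) of a
  requested locus, erroring with the best achieved distance when the locus
  lies outside the family's gamut.
* **Observational assay**: n = 45 spiders (the residual degrees of freedom
  of the observational analysis imply 45), distances uniform on 0–500 cm,
  colour distances computed through the full visual model from generated
  spider/flower pairs, and rates
  `β0 + β_p·d_phys + β_c·d_col + β_pc·d_phys·d_col + ε`. Defaults
  `β = (3.5, −0.003, −2, 0.005)`, `σ = 1` are round numbers on natural
  scales chosen so that colour similarity matters at short range and its
  effect crosses zero within the observed distance range; the published
  observational coefficients are not used directly because their predictor
  scaling is not recoverable from the reported table alone.
* **Factorial experiment**: 24 spiders per cell (96 total), matched =
  yellow morph, mismatched = white, rates = cell mean + Normal(0, σ). The
  generating cell means derive from the reported treatment coefficients
  (intercept 1.79, near +1.69, mismatched +0.02, interaction −0.96 prey/h)
  and σ = 1.15 prey/h, the residual scale implied by the reported standard
  errors; this puts the expected model R² near 0.27.

**What the generators do not emulate:** real floral reflectance diversity
(the family is parametric and smooth), non-uniform natural distance
distributions (so simulated 5th/95th percentiles sit nearer 25/475 cm than
any particular field values), over-dispersed or zero-inflated capture
counts, pollinator behaviour, and spider pattern (banding) as opposed to
colour. Passing tests therefore demonstrate the pipeline's correctness and
statistical calibration, not field-data reproduction.

## Problem sizes and numerical tolerances

The test suite uses the study-scale defaults above plus: 500 observational
replicates of n = 500 for CI-coverage calibration (the 95% CI must cover
each generating coefficient 93–97% of the time), 200 factorial replicates
for interaction-direction recovery, 1000 random loci for the metric
properties, 50 random fixtures for the normal-equations comparison (1e-10),
and 0.1-nm Riemann sums for the integration oracle (0.1%). These sizes make
Monte-Carlo error small relative to each tolerance while keeping the whole
suite quick on a single CPU.

## Known limitations

* Receptor sensitivities are template-generated, not measured; see above.
* The D65 table is the standard 10-nm tabulation interpolated to 1 nm;
  fine solar structure is irrelevant at the smoothing scales used.
* The Gaussian rate model can predict negative rates; for very low capture
  rates a count model would be more faithful (deliberately out of scope).
* `all_subsets()` refits each candidate by `lm`; at 19 candidates this is
  instantaneous, but the enumeration grows exponentially with additional
  global terms.
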