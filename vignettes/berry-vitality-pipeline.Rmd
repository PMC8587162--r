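---
title: "Berry cell vitality from images, spectra and canopy architecture: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Berry cell vitality from images, spectra and canopy architecture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(grapevit)
```

## The problem

In wine grapes, mesocarp cells begin dying from roughly 90–100 days after
anthesis. The extent of this berry cell death (BCD) shapes flavor and aroma
development, so it is a candidate objective maturity measure. The direct
assay is laborious: berries are halved, stained with fluorescein diacetate
(FDA) — which living cells hydrolyze to green-fluorescent fluorescein — and
imaged under a fluorescence microscope; the share of mesocarp area that
fluoresces is the percent living tissue (LT), and BCD = 100 − LT.

`grapevit` implements a tested pipeline around this assay and the two
indirect routes to it:

1. **berry_vitality** — image quantification of %LT/%BCD from FDA images;
2. **canopy_architecture** — gap-fraction analysis of upward-looking
   ("cover photography") canopy photographs into six canopy parameters;
3. **nir_chemometrics** — Savitzky–Golay derivative preprocessing of
   handheld NIR absorbance spectra of intact berries;
4. **ann_regression / evaluation** — shallow feedforward regression
   networks mapping NIR features (Model 1) or canopy parameters (Model 2)
   to LT/BCD, and canopy parameters to ten wine sensory descriptor
   intensities (Models 3–4), with the accuracy, prediction-bound-outlier
   and ANOVA/Tukey statistics used to judge them;
5. **synthetic_data** — seeded generators for all four input kinds with
   known ground truth, so every stage is testable without field data.

No field data are distributed with the study this pipeline re-implements,
so the synthetic generators are first-class, tested code: they define the
conditions under which the pipeline's accuracy claims are verified.

## Canopy architecture from cover photography

An upward photograph is thresholded on its **blue channel** (sky/foliage
contrast is best in blue for upward images; the channel is configurable)
with Otsu's method by default. With `gT` the total sky-gap fraction and
`gL` the fraction in *large* gaps (8-connected sky components of at least
1% of the frame — the between-crown gaps), the six parameters are

- canopy cover `fc = 1 − gT`,
- crown cover `ff = 1 − gL`,
- crown porosity `Φ = 1 − fc/ff`,
- leaf area index `LAI = −ff·ln(Φ)/k` (Beer–Lambert with extinction
  coefficient `k`),
- clumping index `Ω = (1 − Φ)·ln(1 − fc)/(ln(Φ)·fc)`,
- effective LAI `LAIe = Ω·LAI`.

Numerical choices:

- `k = 0.7` by default. Published grapevine group means are internally
  consistent with the LAI equation only near this value (e.g. crown cover
  0.84 and porosity 0.19 give `−0.84·ln(0.19)/0.7 = 1.99` against a
  printed mean of 2.00); `k` is exposed in every interface.
- `Φ` is clamped to `[1e−6, 1 − 1e−6]` before logarithms so degenerate
  (all-sky, all-canopy) images yield finite flagged results instead of
  infinities; clamping is recorded as a warning in the result.
- `Ω = 1` by convention when `fc` is 0 or 1 (the limit value).
- The large-gap area threshold (default 1% of the frame) is configurable;
  it only affects `ff` on real images, and published sources for the
  method do not print the exact criterion.
- Gap components use 8-connectivity, so diagonal speckle merges into
  single gaps — the conservative choice for large-gap detection.
- Per-plant values are the mean of the two (east/west) side images.

`analysis/03_canopy_engine_checks.R` recomputes Φ, LAI and Ω from printed
group-mean cover fractions of field-grown Chardonnay and Shiraz
(`canopy_reference_means()`): `1 − fc/ff` reproduces the printed porosity
at 2 dp in five of six groups. The exception (printed fc 0.49, ff 0.67,
Φ 0.28; recomputed 0.27) is a rounding artifact of the 2-dp printed means
— means such as fc 0.485, ff 0.674 round to the printed values and give
0.28 — and is reported as computed, not patched.

## Berry vitality from FDA fluorescence images

The berry outline is segmented on mean-channel brightness (Otsu), closed
with a disc brush (radius 3 px), hole-filled, and the largest 8-connected
component is kept; a berry smaller than 1% of the frame is an error.
Living tissue inside the outline is scored by **green dominance**
`g − max(r, b)` and thresholded by Otsu over the interior scores. Two
guards matter:

- the threshold never drops below 0, so only genuinely green-dominant
  pixels can count as living;
- when the Otsu split does not separate two real classes (interior score
  means closer than 0.15 — an all-living or all-dead berry is unimodal
  and Otsu would halve the noise), the threshold falls back to the sign
  rule `score > 0`.

The seed region — excluded manually in the original assay because seeds
sit inside living tissue and would inflate BCD — is supplied as a polygon
and rasterized by even-odd ray casting. With `effective = berry \ seed`:
`LT% = 100·|lt ∩ effective|/|effective|`, `BCD% = 100 − LT%`. Masks export
to PNG by default (binary masks survive the round trip losslessly); JPG is
kept for compatibility with legacy archives and costs up to ~0.5
percentage points on re-analysis.

## NIR preprocessing

Spectra live on the instrument's uniform 1596–2396 nm grid. The pipeline
fixes the operation order:

1. **Savitzky–Golay first derivative** over the full instrument range
   (default window 9 points, polynomial order 2 — conventional for
   handheld-NIR resolution; both configurable). Edge points come from the
   polynomial fitted in the terminal window, so the filter is exact on
   polynomials up to the fit order everywhere.
2. **Band selection** to the modelling window, 1596–1919 nm by default.
   Slicing after differentiation keeps filter edge transients out of the
   modelling band (they then sit only at the band's outer edges, which is
   tested explicitly).
3. **Replicate averaging** (three readings per berry) last. Both the
   derivative and the mean are linear, so this order is immaterial
   mathematically; it is fixed for reproducibility.

The study text is not consistent about the modelling band (a discussion
passage mentions 1300–1830 nm, below the instrument's lower limit); the
package follows the 1596–1919 nm band used by the methods and results
tables, and this choice is surfaced here rather than hidden.

## Network training

Networks are one hidden layer of tan-sigmoid units with a linear output
layer; inputs and targets are min-max scaled to [−1, 1] (the standard
companion of tanh hidden layers; scaling uses the full dataset so that a
fit is a deterministic function of data, split and seed). Weights start
from a seeded Nguyen–Widrow-style initialization. The error Jacobian is
assembled analytically by per-sample backpropagation and checked against
central finite differences in the tests.

**Levenberg–Marquardt (LM)** minimizes the summed squared scaled error
`E_D`. Each iteration solves `(JᵀJ + μI)δ = −Jᵀe`; μ divides by 10 on an
accepted (improving) step and multiplies by 10 otherwise. Stops: 1000
epochs, μ > 1e10, gradient infinity-norm < 1e−7, or six consecutive
validation-MSE increases (weights revert to the best-validation epoch).
Models 2–4 use LM with a 60/20/20 train/validation/test split.

**Bayesian regularization (BR)** minimizes `F = β·E_D + α·E_W` with
`E_W = ½Σw²`, using the same damped step on `F`. After each accepted step
the effective number of parameters is re-estimated from the evidence
framework: with the Gauss–Newton Hessian `H = 2β·JᵀJ + αI`,
`γ = N_w − α·tr(H⁻¹) ∈ [0, N_w]`, then `α = γ/(2E_W)` and
`β = (N − γ)/(2E_D)`, starting from `α = 0, β = 1`. This form is used
because it is the self-consistent one: it sends `γ → 0` and the weights
to zero on pure-noise targets (verified in the tests), which an
alternative bookkeeping with a halved Hessian fails to do. BR uses no
validation stage; Model 1 uses BR with a 75/25 train/test split. If the
weights collapse exactly to zero while `γ > 0`, α is capped at 1e10 with
a warning.

**Splits** are seeded uniform permutations. Non-training stages receive
`floor(fraction·n)` samples and training the remainder — the allocation
that reproduces the published stage counts at n = 432 (324/108 at 75/25;
260/86/86 at 60/20/20). Validation/testing counts are always within one
of `fraction·n`; training absorbs both rounding remainders (at most 2).

**Neuron trimming** trains one model per candidate hidden size
(default 3, 5, 7, 10) with a shared seed and split. A candidate is
admissible when `MSE_train ≤ MSE_test` and, when a validation stage
exists, `|MSE_val − MSE_test| ≤ 0.25·MSE_test` (the no-under/overfitting
screen). Among admissible candidates the highest overall R wins; R values
within 1e−3 count as ties and resolve toward fewer neurons (parsimony).
If nothing is admissible the best-R candidate is returned flagged.

## Evaluation statistics

Multi-target models pool their errors: "observations" = samples × targets
(432 samples × 2 targets = 864; 216 × 10 = 2160), matching the published
accounting. Per stage, the package reports Pearson R and the least-squares
slope of predicted on observed (both on the flattened observations) and
the MSE in target units. Outliers are counted against the two-sided
t-based 95% **prediction interval** (including leverage) of the pooled
predicted-vs-observed OLS fit — the default meaning of "95% prediction
bounds" in the plotting tools such figures come from; whether per-stage or
pooled fits were used originally is not stated, and the pooled fit is
assumed. Group comparisons use one-way ANOVA with Tukey HSD and a compact
letter display (`multcomp`); all-identical values return p = 1 by
convention.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of their seed, and every artifact
carries its ground truth.

- **Berry images**: elliptical berry on a dark background; the interior is
  partitioned by a smoothed Gaussian random field into fluorescent-green
  and dull-brown regions with the living pixel count hit exactly by
  construction (top-k of the field); optional pale seed ellipse; Gaussian
  pixel noise (sd 0.02). Not emulated: stain-intensity gradients,
  specular highlights, out-of-focus edges, partial berries.
- **Canopy scenes**: white sky, full-height between-crown gap strips whose
  pixel count realizes `1 − ff` exactly, and within-crown speckle
  (kept ≥ 2 px from crown borders so it cannot 8-connect with a large gap)
  realizing Φ exactly; hence `fc = ff(1 − Φ)` holds to the pixel. Not
  emulated: sky-brightness gradients, leaf translucency, lens distortion.
- **NIR spectra**: smooth baseline plus fixed Gaussian overtone bands plus
  one band at 1620 nm (the hydrogen-peroxide overtone region associated
  with cell death) whose amplitude is affine in the berry's BCD; three
  replicates per berry with iid noise. Not emulated: scatter effects,
  instrument drift, water-band dominance.
- **Vineyard tables**: canopy parameters drawn in the regime of published
  field group means (crown cover 0.55–0.90, porosity 0.13–0.31), with the
  cover-photography identities holding exactly; LT and the ten sensory
  descriptors (named exactly as on the tasting questionnaire, per
  cultivar) come from fixed bounded tanh teacher maps, so 3–10-neuron
  networks can realize them. The LT noise sd defaults to 1 percentage
  point: this was calibrated, as the generator's defining condition, so
  that the canopy-to-vitality model at n = 432 sits in the R ≈ 0.98
  accuracy regime of the field study (verified over 10 seeds in the
  tests). The sensory noise (0.2 cm on a 15 cm scale) likewise targets
  the R ≈ 0.99 regime.

Passing recovery tests on these scenes shows the *arithmetic and the
algorithms* are right; it does not certify segmentation accuracy on real
microscopy or field photographs, where illumination and texture are far
richer.

## Problem sizes used in the tests and scripts

The shipped tests and analysis scripts run the full-size bookkeeping
(432 samples, 864/2160 observations) wherever the quantity is about
counts, and moderate sizes for iterative training demonstrations
(150–432 samples, hidden sizes 3–10, epoch caps 120–300). These sizes are
the package's own choice of demonstration scale; all of them are
parameters, and nothing in the code depends on them.

## Known limitations

- Berry seed regions are supplied manually (as in the original assay);
  automatic seed detection is out of scope.
- No scatter correction (SNV/MSC) or calibration transfer for NIR.
- The ANN module implements exactly the two training algorithms the
  models use (LM, BR); no other optimizers, no deep architectures.
- ANOVA is one-way only; no mixed or repeated-measures designs.
- How the original study assembled 216 samples per cultivar for the
  sensory models from nine vines and three wine groups is not stated;
  the vineyard generator parameterizes the sample count freely.
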