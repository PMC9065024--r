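---
title: "Polarimetric entropy imaging of RPE melanin: models and methods"
author: "rpeEntropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarimetric entropy imaging of RPE melanin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpeEntropy)
```

## The measurement model

A Jones-matrix PS-OCT system records at every pixel a 2×2 complex matrix
`J` describing how the sample transforms the polarization state of
backscattered light. Melanin granules in the retinal pigment epithelium
(RPE) depolarize: within a small neighbourhood the measured `J` varies
randomly, while in non-depolarizing tissue it is locally deterministic up
to speckle amplitude and a common phase.

The package quantifies this randomness via the coherency matrix of the
vectorised Jones matrix `t = vec(J)` (column-stacking order
`J11, J21, J12, J22` — the entropy is invariant to the convention, but
one fixed order keeps round-trips consistent):

$$C = \frac{1}{N}\sum_{i=1}^{N} t_i t_i^\dagger,$$

a 4×4 Hermitian positive-semidefinite matrix. Its eigenvalues
`λ₁..λ₄`, normalised to `p_i = λ_i/Σλ`, give the polarimetric entropy

$$E = -\sum_i p_i \log_4 p_i \in [0,1],$$

with `0·log 0 = 0`. The base-4 logarithm normalises the 4-dimensional
spectrum so that a rank-one coherency (uniform polarization) gives 0 and
the maximally mixed coherency `I/4` (completely random polarization)
gives 1. Because `E` depends on `C` only through its spectrum, applying
unitaries `J → U J V` — a change of the incident or detected polarization
basis — leaves it unchanged; the test suite verifies this to 1e−10.

### Noise-bias correction

Additive circular complex detector noise of power `σ²` per Jones element
contributes `σ²I` to the expected coherency and biases entropy upward on
strongly polarized pixels. `noiseBiasCorrect` subtracts `σ²I` and clips
negative eigenvalues to zero — the minimal perturbation restoring
positive-semidefiniteness; trace normalisation is deferred to the entropy
computation. The cited hardware's own estimator is not public, so `σ²` is
estimated from a user-designated signal-free region
(`estimateNoiseSigma2`); the pipeline uses the vitreous rows above the
highest ILM position. Degenerate pixels whose corrected coherency has
zero trace are flagged `NA` rather than raising an error.

### Kernel averaging

`entropyMap` estimates `C` per pixel over a 5 × 11 (depth × transverse)
kernel — the acquisition setting this package mirrors. Kernels are
truncated at image borders and averaged over the available pixels only:
padding would fabricate polarization states. Whether the instrument
averages coherently or incoherently before forming `C` is not documented;
truncated incoherent averaging is assumed. The per-pixel eigen-decomposition
runs in compiled code (RcppArmadillo) with summed-area tables for the
kernel sums; the R-level `coherencyMatrix`/`entropyFromCoherency` route is
the reference implementation against which the compiled path is tested.

## The synthetic-data generator

No public dataset accompanies the measurement protocol, so the generator
is a first-class module: every downstream stage is validated against its
analytic ground truth.

**Depolarization mixture.** At each RPE-band pixel the vectorised Jones
matrix is, with probability `m(col)`, an isotropic Haar-random unit
vector in ℂ⁴, and otherwise a fixed column-dependent target vector `t₀`.
The ensemble coherency is then

$$C = (1-m)\,t_0 t_0^\dagger + \frac{m}{4} I,$$

with eigenvalues `{(1−m)+m/4, m/4, m/4, m/4}` and the closed-form entropy
`closedFormEntropy(m)`, strictly increasing from 0 to 1. This mixture was
chosen precisely because it admits an analytic oracle; physical melanin
depolarization (multiple scattering from nonspherical granules) has no
such closed form.

**Speckle and noise.** Fully developed speckle multiplies each pixel's
vector by an independent circular complex Gaussian amplitude (Rayleigh
modulus) — standard OCT statistics. Additive circular complex Gaussian
noise is applied per element at a configurable SNR, defined relative to
the mean RPE signal power summed over the four elements
(`σ² = 10^(−SNR/10)/4`). The default is 25 dB, a typical RPE-level SNR
for macular OCT; speckle defaults on. Non-RPE tissue uses a background
mixture value 0.05, the choroid 0.35, and the vitreous is signal-free so
noise can be estimated from it.

**Geometry.** Defaults mirror the acquisition this package targets:
6 × 6 mm raster, 1024 A-scans × 256 B-scans, 5.86 × 4.2 µm pixels. The
axial depth count is not fixed by that protocol; the default of 512 rows
covers retina and choroid at 4.2 µm. The depolarizing RPE band is 8 px
(~34 µm) thick. The melanin profile presets are `monotone`
(`floor + (peak−floor)·exp(−|d|/decay)`), `flat`, and `step`. The
monotone defaults (peak 0.20, floor 0.08, decay 1.6 mm) were set so the
closed-form entropies at the fovea and at ±2 mm (~0.42 and ~0.28) match
the scale reported for RP eyes; they are study conditions, not tuning
knobs.

**AF scenes.** NIR-AF intensity is proportional to melanin plus a single
additive choroidal constant (the simplest confounder sufficient to test
discrepancy analyses); SW-AF is lipofuscin × (1 − macular-pigment
attenuation) with an annular hyperautofluorescent ring multiplier at the
EZ-border radius. Scenes are analytic radial functions evaluated through
a known affine transform (device geometry composed with a
rotation/scale/translation misalignment), so landmark pairs are exact
before jitter.

**What the generator does not emulate:** wave propagation, multiple
scattering, media opacity, axial-length variation, eye motion, vessel
shadows, or elastic (non-affine) distortion between AF and OCT. Passing
tests demonstrate correctness of the estimators under the stated
statistical model, not robustness to these real-data effects.

## Profiles and morphometry

The RPE-line entropy is the mean within six pixels (25 µm) of the
segmentation line. The six-row window is placed 3 px above and 2 px below
the half-up-rounded line plus the line pixel — an even window has no
symmetric centring, and this split is the most symmetric choice; the
alternative (2 above/3 below) changes section means by less than the
estimator noise. Fractional trace depths are rounded half-up for
platform-stable reproducibility.

Per-column values are binned into 0.25-mm sections: column offsets
`(col − fovea)·dx` in mm, the foveal section covering
`[−0.125, 0.125)` mm, unweighted means per section (weighting by
valid-pixel count is unspecified upstream; unweighted was chosen), and
edge sections with under half the nominal ~42⅔ columns dropped, since
partial sections are not reported in practice. Left-eye profiles are
mirrored so the temporal side is always negative; orientation is recorded
and can be applied exactly once. The fovea is an operator-supplied column
(or synthetic truth) — the clinical identification via the foveal bulge
is manual and out of scope, as is automatic layer segmentation.

EZ width converts a column span to µm by `widthMm·1000/nCols`; CRT is the
ILM-to-inner-RPE distance at the foveal column times the axial pitch.

## AF registration and normalization

Elastic B-spline registration used in clinical workflows is replaced by
landmark-driven least-squares affine fitting: macular deformations
between the en-face OCT projection and a fundus camera are small, and an
affine model is deterministic, dependency-light, and directly testable
against the generator's ground-truth transform (median grid error under
1 px with 6 landmarks and 0.5-px jitter). At least 3 non-collinear pairs
are required; the RMS residual is reported. Warping uses inverse-mapped
bilinear resampling with out-of-bounds mapped to 0.

AF intensity is sampled along the single row corresponding to the foveal
B-scan (a line, not a band), sectioned exactly like the entropy profile,
and min–max normalized per eye — a simplified internal AF reference that
makes intensities comparable across participants. Normalization operates
on section means rather than raw pixels (ambiguous upstream; section
means are what enter the correlations) and is idempotent and invariant to
positive affine rescaling.

## Statistics

- `spearmanCorr`: Pearson correlation of average ranks; exact permutation
  p (all `n!` arrangements, compiled) for n ≤ 10, t-approximation above.
- `rankSumTest`: Mann–Whitney U via `stats::wilcox.test`, exact null
  enumeration when `n_a + n_b ≤ 12` without ties, tie-corrected normal
  approximation otherwise; validated against brute-force enumeration of
  every tie-free arrangement up to 6 + 6. The upstream analysis applies a
  rank-sum test to per-eye paired sections; the package implements the
  test exactly as named (unpaired) rather than silently substituting a
  signed-rank test.
- `bonferroni`: `min(1, p·k)`; both raw and adjusted p-values are
  reported because the correction convention behind published section
  p-values is not recoverable; only the significance pattern is asserted.
- `summarizeCohort`: sample (n−1) SDs for all `±` values.
- `pooledAFCorrelation` pools (entropy, AF) section pairs across all eyes
  after per-eye normalization, matching sections by bin center — naive
  pooling without within-eye correlation modelling, as in the reference
  analysis.

## Problem sizes and reproducibility

Simulation-based checks run on single-B-scan volumes of 1024 columns ×
140 depth rows (the full transverse extent, a reduced depth range
containing all layers) and 12-eye studies at 192 × 1024 × 64; these sizes
give per-section standard errors well below the effects under test while
keeping the full suite fast. All randomness flows through explicit
integer seeds; volumes, scenes, cohorts and reports are bit-reproducible
per seed.

The end-to-end recovery check uses a monotone phantom spanning the full
mixture range (peak 0.6, floor 0.05, decay 2 mm). With the cohort-scale
default profile, adjacent sections differ by ~0.01 in expected entropy —
below the single-B-scan estimator's per-section precision (~0.05) — so
rank agreement there measures noise, not estimator fidelity; the
full-range phantom probes ordering across the dynamic range the method
claims to resolve.

## Known limitations

- The mixture model is a statistical surrogate for melanin
  depolarization; absolute `m` values are not physical melanin
  concentrations.
- Plug-in entropy from 55-sample kernels is biased low by ~0.02–0.04
  (eigenvalue estimation bias); noise-bias correction removes only the
  additive-noise component. Comparisons across eyes processed with the
  same kernel are unaffected.
- Min–max normalization makes AF profiles ordinal rather than
  quantitative; only rank-based pooled statistics are meaningful.
- The affine registration cannot represent the elastic distortions of
  peripheral fundus imaging; it is adequate for the macular field only.
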