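# rpeEntropy

Quantification of retinal pigment epithelium (RPE) melanin from
polarization-sensitive optical coherence tomography (PS-OCT), with
registered fundus autofluorescence (AF) comparison and cohort statistics.

Melanin depolarizes backscattered light. A Jones-matrix PS-OCT system
records, at every pixel, a 2×2 complex Jones matrix `J` describing how the
sample transforms polarization. Over a local ensemble (kernel) of pixels,
the package forms the 4×4 coherency matrix of the vectorised Jones matrix
`t = vec(J)`,

    C = ⟨ t t† ⟩,

and parameterises the spatial randomness of polarization as the
**polarimetric entropy** of its eigenvalue spectrum `λ₁..λ₄`
(`p_i = λ_i / Σλ`):

    E = − Σ p_i log₄ p_i  ∈ [0, 1],

0 for completely uniform polarization (rank-one coherency), 1 for
completely random polarization (`C = I/4`). Entropy is insensitive to the
incident polarization state (unitary invariance) and admits additive
noise-bias correction by subtracting `σ²I` from `C`. In the RPE, entropy
tracks the concentration of melanin granules, making it a layer-specific
melanin contrast for monitoring retinal degenerations such as retinitis
pigmentosa (RP).

The package implements, for a 6 × 6 mm macular raster (1024 A-scans ×
256 B-scans, 5.86 × 4.2 µm pixels):

- **Entropy maps** (`entropyMap`): per-pixel entropy of one B-scan with a
  5 × 11 kernel (truncated at borders) and optional noise-bias correction
  (`noiseBiasCorrect`, `estimateNoiseSigma2`).
- **RPE-line profiles** (`rpeLineEntropy`, `binSections`,
  `orientProfile`, `sectionValue`): the entropy averaged within six pixels
  (25 µm) of the segmented RPE line, binned into 0.25-mm sections relative
  to the fovea, oriented temporal-negative (left eyes mirrored); foveal
  and ±2-mm section values; EZ width and central retinal thickness
  morphometry (`computeEZWidth`, `computeCRT`).
- **AF registration and profiles** (`fitLandmarkTransform`, `warpImage`,
  `afLineProfile`, `minmaxNormalize`): landmark-driven affine registration
  of short-wavelength (lipofuscin) and near-infrared (melanin) AF images
  to the OCT en-face projection (`enFaceMIP`), line sampling along the
  RPE-corresponding row, sectioning, and per-eye min–max normalization.
- **Cohort statistics** (`summarizeCohort`, `sectionComparison`,
  `pooledAFCorrelation`, `clinicalPanel`): Spearman correlations, Wilcoxon
  rank-sum tests with Bonferroni correction, logMAR conversion.
- **Synthetic ground truth** (`makePhantom`, `renderJonesVolume`,
  `renderAFScene`, `makeCohort`, `simulateStudy`): a two-component
  depolarization mixture model — with probability `m` a pixel's `t` is an
  isotropic Haar-random unit vector, otherwise a fixed target vector — so
  the expected entropy has the closed form `closedFormEntropy(m)` with
  eigenvalues `{(1−m)+m/4, m/4, m/4, m/4}`. Every pipeline stage is
  testable against this analytic oracle.

A packaged reference cohort (`referenceCohort()`) carries the demographic
and clinical table of a 12-eye RP case series.

## Worked example

```r
library(rpeEntropy)

rep <- reproduceSummary()     # packaged reference cohort
rep$summary
#>           variable      mean       sd  n
#> 1              age   37.9167 1.22e+01 12
#> 2      logmar_bcva   -0.0537 9.98e-02 12
#> 3    entropy_fovea    0.4083 8.12e-02 12
#> 4 entropy_temporal    0.2908 7.53e-02 12
#> 5    entropy_nasal    0.2617 8.46e-02 12
#> 6      ez_width_um 1991.2500 1.19e+03 12
#> 7           crt_um  224.6667 2.85e+01 12
rep$comparisons
#>          comparison   p_raw p_adjusted
#> 1 fovea_vs_temporal 0.00242    0.00726
#> 2    fovea_vs_nasal 0.00134    0.00403
#> 3 temporal_vs_nasal 0.22464    0.67392
```

Mean section entropies round to 0.41 (fovea), 0.29 (temporal) and 0.26
(nasal): RPE melanin is highest at the fovea, and the foveal section
differs significantly from both peripheral sections (adjusted p < 0.05)
while temporal and nasal do not differ. `rep$panel` shows that age, logMAR
acuity, EZ width and CRT are uncorrelated with foveal entropy in this
cohort.

A fully synthetic eye, end to end:

```r
ph  <- makePhantom(nCols = 512, nRows = 160, nBscans = 32)
res <- runEye(ph, NoiseSpec(seed = 9))
sectionValue(res$sectionProfile, "fovea")     # 0.435 (closed form 0.424)
res$ezWidthUm                                 # 2000
spearmanCorr(profileMeans(res$sectionProfile),
             profileMeans(res$afProfiles$NIR))$rho   # 0.616: NIR ~ melanin
```

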