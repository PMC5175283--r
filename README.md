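# msihet

Quantitative analysis of drug distribution heterogeneity in tumor tissue
sections imaged by MALDI mass spectrometry imaging (MSI).

Bulk assays of tumor homogenates report a single drug concentration per
tumor and hide the fact that a drug may saturate well-perfused regions
while barely reaching necrotic or fibrotic ones. MSI resolves the drug
signal per raster pixel (typically 100 × 100 µm), but raw ion intensities
are distorted by *ion suppression*: co-located endogenous species quench
ionization differently in different parts of the tissue, so raw images
confound drug amount with local matrix effects. `msihet` implements an
analysis pipeline for this problem, aimed at pharmacologists and imaging
scientists who want reproducible, quantitative heterogeneity metrics from
MSI data:

- **Internal-standard normalization.** A deuterated analogue of the drug is
  sprayed uniformly over the section, so its per-pixel intensity reports
  the local suppression. For drug channel `D`, standard channel `I` and a
  shared multiplicative suppression field `s`,
  `(s·D) / (s·I) = D / I`: the per-pixel ratio cancels suppression
  exactly. `normalizeIntensity()` computes it with a floor on the
  standard's intensity so ratios stay bounded.
- **Absolute quantification.** Spots of known drug amount (0.2–15 pmol)
  on control tissue give a linear calibration
  `signal = a + b · (amount/area)`; `buildCalibration()` fits it by OLS
  and `quantifyRoi()` inverts it, `amount = (signal − a)/b`, expressing
  any ROI in pmol/mm².
- **Heterogeneity metrics.** `estimateThreshold()` sets a positivity
  cutoff `mean + k·sd` from untreated control sections; the coverage
  metric is the percent of tissue pixels whose normalized signal exceeds
  it (`percentPositive()`), and `particleAnalysis()` measures the
  connected clusters of positive pixels (count, size, perimeter,
  circularity), in the spirit of ImageJ's particle analysis.
- **Zonation.** `zoneMap()` re-bins a section into high (≥ 75 % of the
  section maximum), mid (25–75 %) and low (< 25 %) intensity zones;
  randomly placed 25-pixel circular ROIs per zone are quantified
  absolutely and summarized as fold ratios high/low and high/mid
  (`sampleZoneRois()`, `zoneQuantify()`).
- **Phantoms with ground truth.** `makePhantom()` simulates tumor sections
  (homogeneous, necrotic-core, patchy-vascular, fibrotic, scant
  archetypes) through an explicit forward model — drug density ×
  suppression field × noise + background, plus a sprayed-standard
  channel — so every metric above can be validated against known truth.
- **I/O and statistics.** imzML 1.1 (+ ibd) and plain CSV grids
  (`readGrid()`, `writeGrid()`, `readImzML()`); one-way ANOVA with
  Tukey's multiple comparisons across tumor models (`compareGroups()`);
  `runPipeline()` runs everything end to end with full seed provenance.

## Worked example

Simulate a calibration section, untreated controls and a tumor phantom
with patchy vascular drug penetration, then quantify it:

```r
library(msihet)

cal   <- makeCalibrationSection(seed = 2)
curve <- buildCalibration(cal$spots, normalizeIntensity(cal$drug, cal$istd))
curve
#> CalibrationCurve: signal = 0.008647 + 0.09938 * amount  (R^2 = 1.0000)
#>   6 points, calibrated range 0.8-60 pmol/mm^2
rSquared(buildCalibration(cal$spots, cal$drug))  # raw, un-normalized
#> [1] 0.976

controls <- lapply(1:9, function(i) {
  cs <- makeControlSection(sMin = 0.4, sMax = 1.0, seed = 100 + i)
  normalizeIntensity(cs$drug, cs$istd)
})
thr <- estimateThreshold(controls, k = 3)
thr
#> ThresholdModel: threshold = 0.01222 (mean 0.007468 + 3 sd 0.001585; 32400 control pixels)

ph   <- makePhantom(phantomConfig(archetype = "patchy_vascular", seed = 3))
sec  <- getSection(ph$stack, 1)
norm <- normalizeIntensity(sec$drug, sec$istd)
percentPositive(norm, thr)                         # 73.5
100 * ph$truth[[1]]@positiveSupportFraction        # 73.5 (ground truth)
particleAnalysis(norm, thr)
#> ParticleStats: 1 particles (8-connectivity)
#>   mean size 1.69e+03 px (16.86 mm^2), mean perimeter 34.6 mm, mean circularity 0.177
homogenateEquivalent(norm, curve)$amount           # 1.19 pmol/mm^2
```

The normalized calibration is essentially perfectly linear (R² = 1.000)
while the raw curve, degraded by per-spot suppression, reaches only
R² = 0.976 — the quantitative benefit of the sprayed internal standard.
The percent-positive metric recovers the phantom's true drug support to
the first decimal, and the bulk homogenate-equivalent amount (1.19
pmol/mm²) alone would say nothing about the 26 % of tissue the drug never
reached.

Zonal quantification on a designed-contrast phantom whose three density
plateaus are exactly known:

```r
zp    <- makeZonedPhantom(phantomConfig(seed = 5))
zsec  <- getSection(zp$stack, 1)
znorm <- normalizeIntensity(zsec$drug, zsec$istd)
rois  <- sampleZoneRois(zoneMap(znorm, thr), seed = 6)
zoneQuantify(znorm, rois, curve, seed = 6)
#> ZoneQuantReport (pmol/mm^2):
#>  zone meanAmount    sdAmount nRois
#>  high   5.000544 0.044656170     3
#>   mid   2.393384 0.006684019     3
#>   low   1.036940 0.016141322     3
#>   fold high vs low: 4.82; high vs mid: 2.09
```

The recovered zone amounts match the designed densities (5, 2.39 and
1.05 pmol/mm²) and the fold ratios the designed contrast.

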