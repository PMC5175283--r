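---
title: "Methods: models, parameters and design choices in msihet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in msihet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msihet)
```

# The measurement model

A MALDI-MSI acquisition rasters a tissue section (pixel edge typically
100 µm) and records one mass spectrum per pixel. An *ion image* for a
channel of interest is the per-pixel sum of spectral intensities inside a
closed m/z window `[mz − tol, mz + tol]` (`extractIonImage()`). The
window half-width `tol` defaults to 0.25 Da, a width that separates a
drug fragment at m/z 284.2 from its deuterated analogue at 289.2 with a
wide margin on a reflectron-TOF mass axis; instruments and processing
software differ here, so `tol` is exposed everywhere and stored with the
image. The window is a *closed* interval and the summary is a *sum* (not
a maximum), so partitioning a spectrum into sub-windows is exactly
additive.

The observed drug intensity at pixel p is modelled as

```
drug[p] = gain * density[p] * s[p] * noise_d[p] + bg[p]
istd[p] = I0               * s[p] * noise_i[p] + bg[p]
```

where `density` is the drug amount per area (pmol/mm²), `s` is a
spatially smooth multiplicative ion-suppression field shared by the two
channels, `I0` the nominal intensity of the uniformly sprayed internal
standard, `noise_*` independent unit-mean multiplicative noises and `bg`
an additive background. This factorization is the assumption that makes
ratio normalization work: a deuterated standard co-crystallizes and
ionizes like the analyte, so suppression enters both channels through the
same factor and

```
(s · D) / (s · I) = D / I
```

pixel by pixel. `normalizeIntensity()` computes this ratio on the
intersection of the two masks. Pixels whose internal-standard intensity
falls below a floor are masked rather than divided: clipping would
silently produce unbounded ratios where the standard's signal carries no
information. The floor defaults to 5 % of the median valid
internal-standard intensity — low enough never to trigger on healthy
spray coverage, high enough to exclude near-zero denominators — and the
number of floor-masked pixels is recorded on the result.

What the ratio does *not* cancel: additive background (chemical noise),
which is divided by `s·I0` and therefore slightly *amplified* in strongly
suppressed regions, and any channel-specific multiplicative noise. Both
effects are represented in the phantom generator and bounded in the
validation suite.

# Absolute quantification

Calibration spots of known amount (defaults 0.2, 0.5, 1.5, 5, 10 and
15 pmol per 25-pixel spot, i.e. 0.8–60 pmol/mm² at 100 µm pixels — six
levels spanning the declared 0.2–15 pmol range on a roughly logarithmic
grid) give points (amount/area, mean signal over the spot's valid
pixels). `buildCalibration()` fits an unweighted ordinary least-squares
line and reports R² as the squared Pearson correlation of the points.
Three choices here were genuinely open and are fixed as follows:

- **Spot summary = mean, not sum.** The abscissa is an amount *per
  surface*; the mean is invariant to spot size, the sum is not.
- **No weighting, intercept free.** Nothing in the calibration design
  motivates a variance model, and a free intercept absorbs the additive
  background offset that survives normalization — which measurably
  improves reverse quantification of weak zones.
- **Extrapolation flagged, not forbidden.** `invertCalibration()` returns
  `(signal − intercept)/slope` for any signal, with flags when the result
  leaves the calibrated range (including negative amounts below the
  intercept); refusing to answer would silently bias downstream means.

# Background threshold and heterogeneity metrics

The positivity cutoff is `mean + k·sd` of the *normalized* signal pooled
over untreated control sections (`estimateThreshold()`), with `k = 3` by
default: under a Gaussian background this passes ≈ 0.13 % of
drug-free pixels, which on a 60 × 60 section is about five false pixels —
negligible against the percent-positive metric's scale. `k` is exposed
because "greater than the background noise" is a policy, not a number.

Pooling matters. A single control section realizes one suppression
field; `mean + 3·sd` from it under-covers the spread of an independent
section's field, inflating false positives in that section's most
suppressed pockets. The validation suite therefore pools nine control
sections (three specimens × three serial sections, the scale of a typical
vehicle-treated control arm), after which support recovery on phantoms is
accurate to about one percentage point. This is a real limitation of
global mean+k·sd thresholding under spatially varying suppression, not an
artifact of the simulation.

`percentPositive()` uses strict exceedance (ties count negative), so the
metric is monotone non-increasing in the threshold. `particleAnalysis()`
labels connected components of the positive mask — 8-connectivity by
default, matching the common ImageJ behaviour; 4-connectivity available —
with per-particle size, perimeter and circularity. Perimeter is the count
of exposed 4-neighbourhood pixel edges times the pixel edge length; this
is simple, exactly testable against a brute-force oracle, and additive
over components, but it is *not* ImageJ's weighted boundary estimate (an
isolated pixel has perimeter 4 edges here). Circularity
`4π·area/perimeter²` is computed in consistent physical units and capped
at 1. No minimum particle size is imposed by default. The labeling itself
is an iterative minimum-label propagation (each positive pixel repeatedly
takes the smallest label in its neighbourhood until a fixed point), which
vectorizes well in R; the test suite proves it identical to flood fill on
all 512 3×3 masks and on random 64×64 masks for both connectivities.

# Zonation

`zoneMap()` re-bins a normalized section relative to its maximum: high
≥ 0.75·max, mid in [0.25, 0.75)·max, low strictly between the background
threshold and 0.25·max, background at or below the threshold. The
boundary fractions are nominally "approximately 75 %/25 %" in the display
convention this mirrors; they are fixed at exactly 0.75/0.25 and
configurable. Two decisions:

- **Robust maximum.** The section maximum defaults to the 99.9th
  percentile of valid pixels so a single hot pixel cannot compress every
  zone; the raw maximum is available via `robustMax = FALSE`.
- **Background excluded from "low".** A display scale runs "to zero", but
  quantifying sub-noise pixels would average noise into the low zone's
  amount, so they are labelled `background` and never sampled.

ROI placement inside zones replaces drawing "representative" circles by
eye with seeded rejection sampling: `sampleZoneRois()` draws 25-pixel
circular ROIs (`makeCircularRoi()` takes the n nearest pixels to a
centre, guaranteeing the exact count that a rasterized radius cannot)
until each ROI is at least 80 % inside its zone (`purity = 0.8`, a
compromise between representativeness and feasibility on speckled zone
boundaries) and ROIs within a zone do not overlap. The draw is fully
determined by its seed, which is recorded in the resulting report.
Fold ratios high/low and high/mid are ratios of per-zone mean amounts;
they are reported as `NA` with a warning if a zone mean is not positive.

# The phantom generator

`makePhantom()` exists so every metric above can be checked against
ground truth. Its defaults are one fixed set of study conditions, chosen
once to represent a realistic acquisition:

| parameter | default | meaning |
|---|---|---|
| `gridShape` | 60 × 60 | 6 × 6 mm section at 100 µm raster |
| `viableDensity` | 5 pmol/mm² | drug level in drug-bearing tissue, mid calibration range |
| `sMin`, `sMax` | 0.4, 1.0 | suppression field bounds (match the per-spot calibration scenario) |
| `correlationLengthPx` | 8 (0.8 mm) | suppression smoothness, tissue-structure scale |
| `istdNominal` | 1000 counts | sprayed-standard intensity |
| `gain` | 100 counts/(pmol/mm²) | detector gain |
| `sprayNoiseCv`, `detectorNoiseCv` | 0.05 each | unit-mean lognormal channel noise |
| `bgScale` | 0.5 | background sd; mean fixed at 10× the sd |
| `nSections`, `spacingUm` | 3, 300 | serial non-adjacent sections |

Lognormal multiplicative noise keeps intensities positive; the additive
background is Gaussian truncated at zero, with its mean held at ten
standard deviations so the truncation is negligible and the Gaussian
tail argument behind `k = 3` applies. The suppression field is low-pass
filtered white noise rescaled min–max to `[sMin, sMax]`, drawn fresh per
section; serial sections jitter the compartment geometry to emulate
non-adjacent cuts. Archetypes idealize histology as macro-scale drug
geometry: a necrotic core, fibrotic lamellae and off-support regions
carry exactly zero drug density (observed signal there is background
only), which both satisfies the "near-zero core" construction and makes
the true positive-support fraction — the target of the percent-positive
validation — well defined. The patchy-vascular archetype decays density
exponentially from seeded vessel points (decay length 300 µm) and
truncates below 10 % of the viable level.

The designed-contrast phantom (`makeZonedPhantom()`) lays three exactly
known density plateaus in bands, by default in the ratios
1 : 1/2.09 : 1/4.76 — plateaus at 100 %, ≈ 48 % and ≈ 21 % of the section
maximum, i.e. centred inside the three zones — so zonal fold recovery has
an exact truth to be compared against. Zone ROI amounts are pooled over
the phantom's three serial sections in the validation, averaging out the
per-section interplay between the suppression-field draw and the
background offset.

What the phantoms deliberately do *not* emulate: MALDI shot statistics,
matrix crystallization, mass-axis drift, peak shapes (intensities are
generated directly as ion images; an optional spectral mode emits
two-peak spectra for exercising extraction and imzML round trips), or
3-D tumor growth. Passing the suite therefore demonstrates the
*analysis* is correct under the stated forward model, not that the model
captures every instrument effect.

# Validation problem sizes

The test suite and `scripts/acceptance.R` use: 100 seeded calibration
sections for the normalized-versus-raw linearity comparison; 20 seeded
fields for exact suppression cancellation (tolerance 1e-10); all 512
3×3 masks plus 100 random 64×64 masks, both connectivities, for particle
labeling; 320 × 320-pixel control pairs (≈ 10⁵ pixels) for the
false-positive rate of `k = 3`; 20 seeds each for support recovery
(±3 percentage points) and fold recovery (±10 %); and 100 seeds for the
RSD-reduction comparison. The RSD suite generates its phantoms with
3.5 % per-channel noise (≈ 5 % combined), the stated condition under
which raw variability is dominated by the shared suppression field; at
the generator's general default of 5 % per channel the comparison can
honestly invert on the rare seed whose tissue-restricted field variation
is smaller than the ratio noise.

# Conventions and numerical details

- Grids are R matrices indexed 1-based as (row, column), row 1 at top;
  a pixel's value refers to its full square; ROI area is
  `n_pixels · (pixel_size/1000)²` mm². The ROI JSON dialect uses the same
  1-based convention.
- imzML I/O supports continuous and processed binary modes with
  uncompressed 64-bit floats, validates the ibd UUID against the XML
  header and the MD5 digest of the binary companion, and bounds-checks
  every external offset/length before reading. The on-disk (x, y)
  positions map to (column, row).
- RSD% is `100·sd/mean` with the sample (n−1) standard deviation,
  defined only for ≥ 2 pixels and positive mean. Raw and normalized RSD
  are always computed over the *same* pixel set (the normalized mask) so
  the comparison is not confounded by masking.
- Series comparisons use Welch's unequal-variance t-test on per-section
  means; identical series with internal variance give t = 0, p = 1, and
  zero-variance input is an error rather than a fabricated p-value.
- Group comparisons use one-way ANOVA with Tukey HSD (Tukey–Kramer for
  unequal n) from base R's `aov`/`TukeyHSD`, flagged at 0.05.
- All stochastic functions take explicit seeds, restore the caller's RNG
  state, and record their seeds in their outputs; `runPipeline()` outputs
  are byte-identical across reruns of the same configuration.

# Known limitations

Peak picking, baseline correction and mass recalibration are out of
scope: inputs are assumed mass-calibrated. Total-ion-current
normalization and suppression-factor calculation approaches are
documented alternatives to the internal-standard ratio but are not
implemented. The global mean+k·sd threshold assumes the pooled controls
represent the treated sections' background; with strongly heteroscedastic
suppression a spatially adaptive threshold would be better than any
global cutoff. Perimeters differ from ImageJ's weighted estimator by
design. Zonation on genuinely homogeneous sections is ill-posed (the
"high" zone reduces to the upper noise tail) and `runPipeline()` reports
those zone columns as `NA` rather than failing the run.
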