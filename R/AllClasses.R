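#' @import methods
NULL

#' IonImage: a single-channel MSI ion image
#'
#' Rectangular per-pixel intensity grid for one extracted m/z channel.
#' Intensities are in arbitrary ion-count units; masked pixels (off-tissue or
#' unacquired) hold \code{NA} in \code{values} and \code{FALSE} in
#' \code{mask}. The pixel size is the physical edge length of one raster
#' pixel, 100 um in a typical acquisition.
#'
#' @slot values numeric matrix of non-negative intensities (\code{NA} where
#'   masked).
#' @slot mask logical matrix, \code{TRUE} = valid pixel.
#' @slot pixelSizeUm physical edge of one pixel in micrometres.
#' @slot targetMz centre m/z of the extracted channel (e.g. 284.2 for the
#'   paclitaxel side-chain fragment, 289.2 for d5-paclitaxel); may be
#'   \code{NA} for derived images.
#' @slot mzTolerance half-width of the extraction window in Da (\code{NA} for
#'   derived images).
#' @slot label free-text provenance (tissue, section index, channel).
#'
#' @seealso [ionImage()], [extractIonImage()], [normalizeIntensity()]
#' @exportClass IonImage
setClass("IonImage",
  slots = c(
    values      = "matrix",
    mask        = "matrix",
    pixelSizeUm = "numeric",
    targetMz    = "numeric",
    mzTolerance = "numeric",
    label       = "character"
  )
)

setValidity("IonImage", function(object) {
  v <- object@values; m <- object@mask
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (!is.logical(m)) return("'mask' must be a logical matrix")
  if (!identical(dim(v), dim(m))) return("'values' and 'mask' must have identical shape")
  if (any(is.na(m))) return("'mask' must not contain NA")
  vv <- v[m]
  if (any(!is.finite(vv))) return("all valid pixel values must be finite")
  if (any(vv < 0)) return("all valid pixel values must be >= 0")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0) return("'pixelSizeUm' must be a single positive number")
  if (length(object@targetMz) != 1L) return("'targetMz' must be length 1")
  if (length(object@mzTolerance) != 1L) return("'mzTolerance' must be length 1")
  if (!is.na(object@mzTolerance) && object@mzTolerance <= 0)
    return("'mzTolerance' must be > 0")
  TRUE
})

#' NormalizedImage: per-pixel drug/internal-standard ratio image
#'
#' Result of dividing a drug ion image by the sprayed internal-standard ion
#' image pixel by pixel. Pixels where the internal-standard intensity falls
#' below \code{istdFloor} are masked rather than divided, so ratios stay
#' finite and bounded.
#'
#' @slot istdFloor minimum internal-standard intensity accepted for division.
#' @slot provenance character(2): labels of the drug and internal-standard
#'   source images.
#' @slot nFloorMasked number of otherwise-valid pixels masked because the
#'   internal standard fell below the floor.
#'
#' @seealso [normalizeIntensity()]
#' @exportClass NormalizedImage
setClass("NormalizedImage",
  contains = "IonImage",
  slots = c(
    istdFloor    = "numeric",
    provenance   = "character",
    nFloorMasked = "integer"
  )
)

#' ROI: a region of interest on a pixel grid
#'
#' An explicit set of (row, col) pixel coordinates (1-based). The physical
#' area is \code{nPixels * (pixelSizeUm/1000)^2} square millimetres.
#'
#' @slot coords integer matrix with two columns (row, col), one row per pixel.
#' @slot pixelSizeUm pixel edge in micrometres, used for area conversion.
#'
#' @seealso [makeCircularRoi()], [pixelRoi()], [areaMm2()]
#' @exportClass ROI
setClass("ROI",
  slots = c(coords = "matrix", pixelSizeUm = "numeric")
)

setValidity("ROI", function(object) {
  co <- object@coords
  if (!is.numeric(co) || ncol(co) != 2L) return("'coords' must be an n x 2 matrix")
  if (nrow(co) < 1L) return("ROI must contain at least one pixel")
  if (any(co < 1) || any(co != round(co))) return("coordinates must be positive integers")
  if (anyDuplicated(paste(co[, 1L], co[, 2L]))) return("duplicate pixel coordinates in ROI")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("'pixelSizeUm' must be a single positive number")
  TRUE
})

#' SectionStack: serial sections of one specimen
#'
#' An ordered list of paired (drug, internal standard) ion images from serial
#' non-adjacent sections of the same specimen, e.g. one section every 300 um.
#'
#' @slot sections list; each element is \code{list(drug = IonImage,
#'   istd = IonImage)}.
#' @slot spacingUm physical distance between consecutive sections (um).
#' @slot subjectId,organ free-text identifiers.
#' @slot group \code{"treated"} or \code{"control"}.
#'
#' @seealso [sectionStack()], [compareSeries()]
#' @exportClass SectionStack
setClass("SectionStack",
  slots = c(
    sections  = "list",
    spacingUm = "numeric",
    subjectId = "character",
    organ     = "character",
    group     = "character"
  )
)

setValidity("SectionStack", function(object) {
  if (length(object@sections) < 1L) return("stack must contain at least one section")
  ps <- NULL
  for (s in object@sections) {
    if (!is.list(s) || !all(c("drug", "istd") %in% names(s)))
      return("each section must be list(drug=, istd=)")
    if (!is(s$drug, "IonImage") || !is(s$istd, "IonImage"))
      return("section channels must be IonImage objects")
    if (!identical(dim(s$drug@values), dim(s$istd@values)))
      return("drug and istd images of a section must share shape")
    if (is.null(ps)) ps <- s$drug@pixelSizeUm
    if (s$drug@pixelSizeUm != ps || s$istd@pixelSizeUm != ps)
      return("all sections must share pixelSizeUm")
  }
  if (length(object@spacingUm) != 1L || object@spacingUm < 0)
    return("'spacingUm' must be a single number >= 0")
  if (!object@group %in% c("treated", "control"))
    return("'group' must be 'treated' or 'control'")
  TRUE
})

#' CalibrationSpot: one spotted calibration droplet
#'
#' A known drug amount (pmol) deposited on control tissue over a known ROI;
#' amount per area (pmol/mm2) is \code{amountPmol / areaMm2(roi)}.
#'
#' @slot roi [ROI-class] covering the spot.
#' @slot amountPmol spotted drug amount in pmol (> 0).
#'
#' @seealso [calibrationSpot()], [buildCalibration()]
#' @exportClass CalibrationSpot
setClass("CalibrationSpot", slots = c(roi = "ROI", amountPmol = "numeric"))

setValidity("CalibrationSpot", function(object) {
  if (length(object@amountPmol) != 1L || !is.finite(object@amountPmol) ||
      object@amountPmol <= 0) return("'amountPmol' must be a single positive number")
  TRUE
})

#' CalibrationCurve: linear signal-versus-amount-per-area model
#'
#' Ordinary least-squares line of mean (normalized) ion signal against
#' spotted drug amount per surface (pmol/mm2), with its inversion contract:
#' \code{amount = (signal - intercept) / slope}.
#'
#' @slot slope signal units per (pmol/mm2).
#' @slot intercept signal units.
#' @slot rSquared squared Pearson correlation of the calibration points.
#' @slot points data.frame with columns \code{amountPerArea} (pmol/mm2) and
#'   \code{meanSignal}, sorted by amount.
#' @slot amountRange numeric(2): calibrated amount range in pmol/mm2.
#'
#' @seealso [buildCalibration()], [invertCalibration()], [quantifyRoi()]
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  slots = c(
    slope       = "numeric",
    intercept   = "numeric",
    rSquared    = "numeric",
    points      = "data.frame",
    amountRange = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  if (nrow(object@points) < 3L) return("calibration requires >= 3 points")
  if (!all(c("amountPerArea", "meanSignal") %in% names(object@points)))
    return("'points' must have columns amountPerArea, meanSignal")
  if (is.unsorted(object@points$amountPerArea))
    return("'points' must be sorted by amountPerArea")
  r2 <- object@rSquared
  if (length(r2) != 1L || r2 < -1e-12 || r2 > 1 + 1e-12)
    return("'rSquared' must lie in [0, 1]")
  if (length(object@amountRange) != 2L || diff(object@amountRange) < 0)
    return("'amountRange' must be c(min, max)")
  TRUE
})

#' ThresholdModel: background positivity cutoff from untreated controls
#'
#' Background statistics of the normalized signal over untreated-control
#' tissue pixels and the derived cutoff \code{threshold = meanBg + k * sdBg}.
#' A pixel counts as drug-positive when its value strictly exceeds the
#' threshold.
#'
#' @slot meanBg,sdBg mean and sample standard deviation of pooled control
#'   pixels.
#' @slot k standard-deviation multiplier (default 3 in
#'   [estimateThreshold()]).
#' @slot threshold the positivity cutoff.
#' @slot nControlPixels number of pooled control pixels.
#'
#' @seealso [estimateThreshold()], [percentPositive()]
#' @exportClass ThresholdModel
setClass("ThresholdModel",
  slots = c(
    meanBg         = "numeric",
    sdBg           = "numeric",
    k              = "numeric",
    threshold      = "numeric",
    nControlPixels = "integer"
  )
)

setValidity("ThresholdModel", function(object) {
  if (object@sdBg < 0) return("'sdBg' must be >= 0")
  if (object@nControlPixels < 2L) return("need >= 2 control pixels")
  TRUE
})

#' ParticleStats: connected-cluster statistics of positive pixels
#'
#' Per-particle table and summary statistics of the connected components
#' ("particles") formed by adjacent drug-positive pixels, in the spirit of
#' ImageJ's particle analysis. Perimeter counts exposed 4-neighbourhood
#' pixel edges; circularity is \code{min(1, 4*pi*area/perimeter^2)}.
#'
#' @slot particles data.frame with columns \code{id}, \code{sizePx},
#'   \code{sizeMm2}, \code{perimeterEdges}, \code{perimeterMm},
#'   \code{circularity}.
#' @slot connectivity 4 or 8.
#' @slot pixelSizeUm pixel edge in micrometres.
#'
#' @seealso [particleAnalysis()], [particleSummary()]
#' @exportClass ParticleStats
setClass("ParticleStats",
  slots = c(particles = "data.frame", connectivity = "integer",
            pixelSizeUm = "numeric")
)

#' ZoneMap: three-level intensity zonation of a section
#'
#' Per-pixel zone labels derived from the section maximum: \code{high} for
#' values at or above \code{fHigh * max}, \code{mid} for values in
#' \code{[fLow * max, fHigh * max)}, \code{low} for values above the
#' background threshold but below \code{fLow * max}, \code{background} at or
#' below the threshold, and \code{masked} outside the tissue mask.
#'
#' @slot labels character matrix with entries in
#'   \{high, mid, low, background, masked\}.
#' @slot fHigh,fLow zone boundaries as fractions of the section maximum.
#' @slot sectionMax the maximum used (robust by default, see [zoneMap()]).
#' @slot backgroundThreshold positivity cutoff separating background.
#'
#' @seealso [zoneMap()], [sampleZoneRois()], [zoneQuantify()]
#' @exportClass ZoneMap
setClass("ZoneMap",
  slots = c(
    labels              = "matrix",
    fHigh               = "numeric",
    fLow                = "numeric",
    sectionMax          = "numeric",
    backgroundThreshold = "numeric"
  )
)

setValidity("ZoneMap", function(object) {
  if (!all(object@labels %in% c("high", "mid", "low", "background", "masked")))
    return("labels must be high/mid/low/background/masked")
  if (!(object@fLow > 0 && object@fLow < object@fHigh && object@fHigh < 1))
    return("need 0 < fLow < fHigh < 1")
  TRUE
})

#' ZoneQuantReport: per-zone absolute quantification and fold ratios
#'
#' Mean drug amount (pmol/mm2) in random circular ROIs per intensity zone and
#' the fold ratios of the high zone over the low and mid zones.
#'
#' @slot zones data.frame with columns \code{zone}, \code{meanAmount},
#'   \code{sdAmount} (NA with a single ROI), \code{nRois}.
#' @slot foldHighVsLow,foldHighVsMid fold ratios (NA when undefined).
#' @slot rois the ROI sets used, named list by zone.
#' @slot seed RNG seed used for ROI sampling (NA if ROIs were supplied).
#'
#' @seealso [zoneQuantify()]
#' @exportClass ZoneQuantReport
setClass("ZoneQuantReport",
  slots = c(
    zones         = "data.frame",
    foldHighVsLow = "numeric",
    foldHighVsMid = "numeric",
    rois          = "list",
    seed          = "numeric"
  )
)

#' PhantomTruth: ground truth for one synthetic section
#'
#' The generative state behind a phantom section: true drug density map,
#' compartment labels, the ion-suppression field, the true positive-support
#' fraction (share of tissue pixels with non-zero drug density), and, for
#' designed-contrast phantoms, the true per-zone densities.
#'
#' @slot densityMap numeric matrix, true drug density in pmol/mm2 (NA off
#'   tissue).
#' @slot compartmentMap character matrix (viable/necrotic/fibrotic/none/off).
#' @slot suppressionField numeric matrix in (0, 1].
#' @slot positiveSupportFraction fraction of tissue pixels with density > 0.
#' @slot zoneDensities named numeric (high/mid/low) for designed-contrast
#'   phantoms, otherwise length 0.
#'
#' @seealso [makePhantom()], [makeZonedPhantom()]
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  slots = c(
    densityMap              = "matrix",
    compartmentMap          = "matrix",
    suppressionField        = "matrix",
    positiveSupportFraction = "numeric",
    zoneDensities           = "numeric"
  )
)

#' PixelSpectra: per-pixel mass spectra with raster coordinates
#'
#' A minimal container for rasterized MSI spectra: one m/z and intensity
#' vector per acquired pixel, with (row, col) coordinates and the acquired
#' m/z range. This is the input of [extractIonImage()] and the unit of
#' imzML input/output.
#'
#' @slot coords integer matrix (n x 2) of 1-based (row, col) coordinates.
#' @slot mz list of numeric m/z vectors, one per pixel.
#' @slot intensity list of numeric intensity vectors, matching \code{mz}.
#' @slot mzRange numeric(2): acquired m/z range, e.g. c(250, 300).
#' @slot pixelSizeUm pixel edge in micrometres.
#'
#' @seealso [pixelSpectra()], [extractIonImage()], [readImzML()]
#' @exportClass PixelSpectra
setClass("PixelSpectra",
  slots = c(
    coords      = "matrix",
    mz          = "list",
    intensity   = "list",
    mzRange     = "numeric",
    pixelSizeUm = "numeric"
  )
)

setValidity("PixelSpectra", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2L) return("'coords' must be an n x 2 matrix")
  if (length(object@mz) != n || length(object@intensity) != n)
    return("'mz' and 'intensity' must have one element per coordinate")
  if (anyDuplicated(paste(object@coords[, 1L], object@coords[, 2L])))
    return("duplicate pixel coordinates")
  if (any(object@coords < 1) || any(object@coords != round(object@coords)))
    return("coordinates must be positive integers")
  for (i in seq_len(n)) {
    if (length(object@mz[[i]]) != length(object@intensity[[i]]))
      return("each spectrum's mz and intensity must have equal length")
  }
  if (length(object@mzRange) != 2L || diff(object@mzRange) <= 0)
    return("'mzRange' must be c(lo, hi) with lo < hi")
  TRUE
})
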