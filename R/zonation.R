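#' Three-level intensity zonation of a normalized section
#'
#' Re-bins a section's normalized signal into high / mid / low intensity
#' zones relative to the section maximum, mirroring a three-colour display
#' scale: high for values at or above \code{fHigh * max}, mid for values in
#' \code{[fLow * max, fHigh * max)}, low for values above the background
#' threshold but below \code{fLow * max}, background at or below the
#' threshold. Sub-threshold pixels are kept out of the low zone so zonal
#' quantification never averages noise.
#'
#' By default the section maximum is a robust maximum (the 99.9th percentile
#' of valid pixels) so a single hot pixel cannot stretch the scale;
#' \code{robustMax = FALSE} uses the raw maximum.
#'
#' @param image a [NormalizedImage-class] (or [IonImage-class]).
#' @param backgroundThreshold numeric or [ThresholdModel-class].
#' @param fHigh,fLow zone boundaries as fractions of the section maximum
#'   (defaults 0.75 and 0.25).
#' @param robustMax use the 99.9th percentile instead of the raw maximum.
#' @return A [ZoneMap-class].
#' @examples
#' img <- ionImage(matrix(c(10, 5, 1, 0.05), 1))
#' zoneLabels(zoneMap(img, 0.1, robustMax = FALSE))
#' @export
zoneMap <- function(image, backgroundThreshold, fHigh = 0.75, fLow = 0.25,
                    robustMax = TRUE) {
  stopifnot(fLow > 0, fLow < fHigh, fHigh < 1)
  thr <- thresholdValue(backgroundThreshold)
  v <- image@values; m <- image@mask
  vv <- v[m]
  if (length(vv) == 0L || all(vv <= thr))
    stop("no signal to zone: every valid pixel is at or below the background threshold")
  mx <- if (robustMax) stats::quantile(vv, 0.999, names = FALSE) else max(vv)
  labels <- matrix("masked", nrow(v), ncol(v))
  labels[m] <- "background"
  pos <- m & !is.na(v) & v > thr
  labels[pos & v < fLow * mx] <- "low"
  labels[pos & v >= fLow * mx & v < fHigh * mx] <- "mid"
  labels[pos & v >= fHigh * mx] <- "high"
  new("ZoneMap", labels = labels, fHigh = fHigh, fLow = fLow,
      sectionMax = mx, backgroundThreshold = thr)
}

#' @rdname accessors
#' @export
setMethod("zoneLabels", "ZoneMap", function(x) x@labels)

setMethod("show", "ZoneMap", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("high", "mid", "low", "background",
                                 "masked")))
  cat(sprintf(
    "ZoneMap: boundaries %.2f/%.2f of section max %.4g (background <= %.4g)\n",
    object@fHigh, object@fLow, object@sectionMax,
    object@backgroundThreshold))
  print(tab)
})

#' Randomly place circular ROIs inside each intensity zone
#'
#' Rejection-samples \code{nPerZone} circular ROIs ([makeCircularRoi()])
#' per zone so that at least \code{purity} of each ROI's pixels carry that
#' zone's label, ROIs within a zone do not overlap, and the draw is fully
#' reproducible from \code{seed}. This is the reproducible analogue of
#' drawing ROIs by eye in representative portions of each colour zone.
#'
#' @param zones a [ZoneMap-class].
#' @param nPerZone ROIs per zone (default 3).
#' @param roiPixels pixels per ROI (default 25).
#' @param purity minimum fraction of in-zone pixels per ROI, in (0.5, 1].
#' @param seed RNG seed.
#' @param pixelSizeUm pixel edge for ROI area conversion.
#' @param zoneNames zones to sample (default high/mid/low).
#' @param maxAttempts rejection-sampling budget per zone.
#' @return named list (by zone) of lists of [ROI-class].
#' @export
sampleZoneRois <- function(zones, nPerZone = 3, roiPixels = 25,
                           purity = 0.8, seed = 1, pixelSizeUm = 100,
                           zoneNames = c("high", "mid", "low"),
                           maxAttempts = 500 * nPerZone) {
  stopifnot(nPerZone >= 1, roiPixels >= 1, purity > 0.5, purity <= 1)
  lab <- zones@labels
  shape <- dim(lab)
  withSeed(seed, {
    out <- list()
    for (zn in zoneNames) {
      cand <- which(lab == zn)
      if (length(cand) == 0L)
        stop("zone '", zn, "' contains no pixels; cannot place ROIs")
      accepted <- list()
      used <- character(0)
      attempts <- 0L
      while (length(accepted) < nPerZone) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
          stop("zone '", zn, "' is too small or fragmented to place ",
               nPerZone, " ROIs of ", roiPixels, " pixels at purity ",
               purity)
        idx <- cand[sample.int(length(cand), 1L)]
        center <- c((idx - 1L) %% shape[1L] + 1L,
                    (idx - 1L) %/% shape[1L] + 1L)
        roi <- makeCircularRoi(center, roiPixels, shape,
                               pixelSizeUm = pixelSizeUm)
        keys <- paste(roi@coords[, 1L], roi@coords[, 2L])
        if (any(keys %in% used)) next
        if (mean(lab[roi@coords] == zn) < purity) next
        accepted[[length(accepted) + 1L]] <- roi
        used <- c(used, keys)
      }
      out[[zn]] <- accepted
    }
    out
  })
}

#' Per-zone absolute quantification and fold ratios
#'
#' Quantifies every supplied ROI through the calibration curve, aggregates
#' per zone (mean, sd in pmol/mm2) and reports the fold ratios of the high
#' zone over the low and the mid zone.
#'
#' @param image a [NormalizedImage-class].
#' @param rois named list (by zone) of lists of [ROI-class], as returned by
#'   [sampleZoneRois()].
#' @param curve a [CalibrationCurve-class].
#' @param seed the seed used to sample the ROIs (recorded for provenance;
#'   \code{NA} if not applicable).
#' @return A [ZoneQuantReport-class]. Folds are \code{NA} (with a warning)
#'   when a zone mean is not positive.
#' @export
zoneQuantify <- function(image, rois, curve, seed = NA_real_) {
  stopifnot(length(rois) >= 1L)
  zones <- do.call(rbind, lapply(names(rois), function(zn) {
    amounts <- vapply(rois[[zn]], function(r)
      quantifyRoi(image, r, curve)$amount, numeric(1L))
    data.frame(zone = zn, meanAmount = mean(amounts),
               sdAmount = if (length(amounts) >= 2L) stats::sd(amounts)
                          else NA_real_,
               nRois = length(amounts), stringsAsFactors = FALSE)
  }))
  getMean <- function(zn) {
    i <- match(zn, zones$zone)
    if (is.na(i)) NA_real_ else zones$meanAmount[i]
  }
  hi <- getMean("high"); lo <- getMean("low"); mi <- getMean("mid")
  bad <- any(!is.na(zones$meanAmount) & zones$meanAmount <= 0)
  if (bad) warning("a zone mean amount is <= 0; fold ratios undefined")
  fold <- function(a, b) {
    if (bad || is.na(a) || is.na(b) || b <= 0) NA_real_ else a / b
  }
  new("ZoneQuantReport", zones = zones,
      foldHighVsLow = fold(hi, lo), foldHighVsMid = fold(hi, mi),
      rois = rois, seed = as.numeric(seed))
}

setMethod("show", "ZoneQuantReport", function(object) {
  cat("ZoneQuantReport (pmol/mm^2):\n")
  print(object@zones, row.names = FALSE)
  cat(sprintf("  fold high vs low: %.3g; high vs mid: %.3g\n",
              object@foldHighVsLow, object@foldHighVsMid))
})

#' Bulk, homogenate-equivalent quantification of a whole section
#'
#' Quantifies the mean normalized signal over every valid tissue pixel —
#' the spatial analogue of assaying a tissue homogenate. Two sections with
#' equal bulk values can have very different spatial heterogeneity reports
#' (percent-positive, particle statistics), which is exactly the contrast
#' this function exists to expose.
#'
#' @param image a [NormalizedImage-class].
#' @param curve a [CalibrationCurve-class].
#' @param tissueRoi ROI covering the section (default: all valid pixels).
#' @return list as for [quantifyRoi()].
#' @export
homogenateEquivalent <- function(image, curve, tissueRoi = NULL) {
  if (is.null(tissueRoi)) tissueRoi <- wholeSectionRoi(image)
  quantifyRoi(image, tissueRoi, curve)
}

#' Export a zone map as an indexed-colour PNG
#'
#' Palette: high = red, mid = green, low = blue, background = black,
#' masked = white.
#'
#' @param zones a [ZoneMap-class].
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeZonePng <- function(zones, path) {
  pal <- list(high = c(1, 0, 0), mid = c(0, 1, 0), low = c(0, 0, 1),
              background = c(0, 0, 0), masked = c(1, 1, 1))
  lab <- zones@labels
  arr <- array(0, c(nrow(lab), ncol(lab), 3L))
  for (zn in names(pal)) {
    sel <- lab == zn
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[sel] <- pal[[zn]][ch]
      arr[, , ch] <- plane
    }
  }
  png::writePNG(arr, path)
  invisible(path)
}
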