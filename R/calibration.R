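#' Declare a calibration spot
#'
#' @param roi [ROI-class] covering the spotted droplet.
#' @param amountPmol spotted drug amount in pmol (> 0); the calibration
#'   abscissa is \code{amountPmol / areaMm2(roi)} in pmol/mm2.
#' @return A [CalibrationSpot-class].
#' @export
calibrationSpot <- function(roi, amountPmol) {
  new("CalibrationSpot", roi = roi, amountPmol = as.numeric(amountPmol))
}

#' Read calibration spot declarations from JSON
#'
#' Expects an array of objects \code{\{"amount_pmol": 0.2, "roi": <roi
#' spec>\}} where the ROI spec follows [readRoiJson()]'s dialect.
#'
#' @param path JSON file.
#' @param gridShape grid dimensions for circle ROI realization.
#' @param pixelSizeUm pixel edge in micrometres.
#' @return list of [CalibrationSpot-class].
#' @export
readCalibrationJson <- function(path, gridShape, pixelSizeUm = 100) {
  specs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(specs, function(s) {
    roi <- if (identical(s$roi$kind, "circle")) {
      makeCircularRoi(as.numeric(unlist(s$roi$center)),
                      as.integer(s$roi$n_pixels), gridShape,
                      pixelSizeUm = pixelSizeUm)
    } else {
      pixelRoi(do.call(rbind, lapply(s$roi$coords, unlist)),
               pixelSizeUm = pixelSizeUm)
    }
    calibrationSpot(roi, as.numeric(s$amount_pmol))
  })
}

#' Build a linear calibration curve from spotted amounts
#'
#' One calibration point per spot: abscissa the spotted amount per surface
#' (pmol/mm2), ordinate the mean (normalized) signal over the spot's valid
#' pixels. An ordinary least-squares line is fitted and its quality
#' summarized by the squared Pearson correlation of the points.
#'
#' @param spots list of [CalibrationSpot-class] with >= 3 distinct amounts.
#' @param image the [NormalizedImage-class] (or raw [IonImage-class]) of
#'   the calibration section.
#' @return A [CalibrationCurve-class].
#' @examples
#' img <- ionImage(matrix(rep(c(3, 5, 9), each = 4), 2))
#' spots <- lapply(1:3, function(i)
#'   calibrationSpot(pixelRoi(cbind(1:2, 2 * i - 1)), c(1, 2, 4)[i] * 0.02))
#' rSquared(buildCalibration(spots, img))
#' @export
buildCalibration <- function(spots, image) {
  if (length(spots) < 3L) stop("calibration requires >= 3 spots")
  amounts <- vapply(spots, function(s) s@amountPmol, numeric(1L))
  if (length(unique(amounts)) < 3L)
    stop("calibration requires >= 3 distinct spotted amounts")
  x <- vapply(spots, function(s) s@amountPmol / areaMm2(s@roi), numeric(1L))
  y <- vapply(spots, function(s) {
    v <- roiValues(image, s@roi)
    if (length(v) == 0L)
      stop("calibration spot has no valid pixels")
    mean(v)
  }, numeric(1L))
  if (stats::sd(x) == 0) stop("zero variance in calibration amounts per area")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  r2 <- stats::cor(x, y)^2
  ord <- order(x)
  new("CalibrationCurve",
      slope = unname(cf[2L]), intercept = unname(cf[1L]),
      rSquared = min(1, max(0, r2)),
      points = data.frame(amountPerArea = x[ord], meanSignal = y[ord]),
      amountRange = range(x))
}

#' @rdname accessors
#' @export
setMethod("rSquared", "CalibrationCurve", function(x) x@rSquared)

#' @rdname accessors
#' @export
setMethod("amountRange", "CalibrationCurve", function(x) x@amountRange)

#' Coefficients of a calibration curve
#' @param object a [CalibrationCurve-class].
#' @param ... ignored.
#' @return named numeric \code{c(intercept, slope)}.
#' @export
setMethod("coef", "CalibrationCurve", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: signal = %.4g + %.4g * amount  (R^2 = %.4f)\n",
    object@intercept, object@slope, object@rSquared))
  cat(sprintf("  %d points, calibrated range %.3g-%.3g pmol/mm^2\n",
              nrow(object@points), object@amountRange[1L],
              object@amountRange[2L]))
})

#' Reverse-quantify a signal through the calibration curve
#'
#' Inverts the calibration line: \code{amount = (signal - intercept) /
#' slope}. Amounts outside the calibrated range (including negative amounts
#' for signals below the intercept) are returned but flagged as
#' extrapolated.
#'
#' @param curve a [CalibrationCurve-class] with positive slope.
#' @param signal mean normalized signal.
#' @return list with \code{amount} (pmol/mm2), \code{extrapolated},
#'   \code{belowRange}, \code{aboveRange}.
#' @export
invertCalibration <- function(curve, signal) {
  if (curve@slope <= 0)
    stop("calibration curve has non-positive slope; cannot invert")
  amount <- (signal - curve@intercept) / curve@slope
  below <- amount < curve@amountRange[1L]
  above <- amount > curve@amountRange[2L]
  list(amount = amount, extrapolated = below | above,
       belowRange = below, aboveRange = above)
}

#' Quantify a ROI in pmol/mm2
#'
#' Mean (normalized) signal over the ROI's valid pixels, inverted through
#' the calibration curve.
#'
#' @param image a [NormalizedImage-class] (or [IonImage-class]).
#' @param roi a [ROI-class] with >= 1 valid pixel.
#' @param curve a [CalibrationCurve-class].
#' @return list with \code{amount} (pmol/mm2), \code{nValidPixels},
#'   \code{extrapolated}.
#' @export
quantifyRoi <- function(image, roi, curve) {
  v <- roiValues(image, roi)
  if (length(v) == 0L) stop("ROI contains no valid pixels")
  inv <- invertCalibration(curve, mean(v))
  list(amount = inv$amount, nValidPixels = length(v),
       extrapolated = inv$extrapolated)
}

#' Serialize a calibration curve to JSON
#'
#' @param curve a [CalibrationCurve-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCalibrationReport <- function(curve, path) {
  jsonlite::write_json(list(
    slope = curve@slope, intercept = curve@intercept,
    r_squared = curve@rSquared,
    amount_range_pmol_mm2 = curve@amountRange,
    points = curve@points), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
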