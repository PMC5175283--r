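#' Accessors for msihet classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{intensityValues()} returns the value matrix of an image,
#' \code{imageMask()} its validity mask, \code{pixelSize()} the pixel edge in
#' micrometres, \code{roiCoords()} the (row, col) coordinate matrix of a ROI,
#' \code{areaMm2()} its physical area, \code{nValidPixels()} the number of
#' valid pixels, \code{rSquared()} and \code{amountRange()} the calibration
#' fit quality and calibrated range, \code{thresholdValue()} the positivity
#' cutoff, \code{zoneLabels()} the per-pixel zone label matrix, and
#' \code{particleTable()} the per-particle data frame.
#'
#' @param x an msihet object.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases intensityValues imageMask pixelSize roiCoords areaMm2
#'   nValidPixels rSquared amountRange thresholdValue zoneLabels
#'   particleTable
#' @examples
#' img <- ionImage(matrix(1:4, 2))
#' intensityValues(img)
#' pixelSize(img)
NULL

#' @rdname accessors
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname accessors
#' @export
setGeneric("imageMask", function(x) standardGeneric("imageMask"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("roiCoords", function(x) standardGeneric("roiCoords"))

#' @rdname accessors
#' @export
setGeneric("areaMm2", function(x) standardGeneric("areaMm2"))

#' @rdname accessors
#' @export
setGeneric("nValidPixels", function(x) standardGeneric("nValidPixels"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("amountRange", function(x) standardGeneric("amountRange"))

#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname accessors
#' @export
setGeneric("zoneLabels", function(x) standardGeneric("zoneLabels"))

#' @rdname accessors
#' @export
setGeneric("particleTable", function(x) standardGeneric("particleTable"))
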