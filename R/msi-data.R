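#' Construct an IonImage
#'
#' @param values numeric matrix of pixel intensities; \code{NA} entries are
#'   masked.
#' @param mask optional logical matrix; defaults to \code{!is.na(values)}.
#' @param pixelSizeUm pixel edge in micrometres (default 100, the typical
#'   imaging raster).
#' @param targetMz,mzTolerance centre and half-width (Da) of the extracted
#'   m/z window; \code{NA} for derived images.
#' @param label free-text provenance.
#' @return An [IonImage-class] object.
#' @examples
#' img <- ionImage(matrix(c(1, 2, NA, 4), 2), targetMz = 284.2,
#'                 mzTolerance = 0.25)
#' nValidPixels(img)
#' @export
ionImage <- function(values, mask = NULL, pixelSizeUm = 100,
                     targetMz = NA_real_, mzTolerance = NA_real_,
                     label = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  values[!mask] <- NA_real_
  new("IonImage", values = values, mask = mask,
      pixelSizeUm = as.numeric(pixelSizeUm),
      targetMz = as.numeric(targetMz), mzTolerance = as.numeric(mzTolerance),
      label = as.character(label))
}

#' @rdname accessors
#' @export
setMethod("intensityValues", "IonImage", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("imageMask", "IonImage", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("pixelSize", "IonImage", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("nValidPixels", "IonImage", function(x) sum(x@mask))

setMethod("show", "IonImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d pixels (%d valid), %g um/pixel\n",
              class(object), d[1L], d[2L], sum(object@mask),
              object@pixelSizeUm))
  if (!is.na(object@targetMz))
    cat(sprintf("  m/z %.4g +/- %.3g Da\n", object@targetMz,
                object@mzTolerance))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
  v <- object@values[object@mask]
  if (length(v))
    cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(v), max(v)))
})

#' Construct a SectionStack of serial sections
#'
#' @param sections list of \code{list(drug = IonImage, istd = IonImage)}
#'   pairs, ordered along the cutting axis.
#' @param spacingUm distance between consecutive sections in micrometres
#'   (default 300).
#' @param subjectId,organ free-text identifiers.
#' @param group \code{"treated"} or \code{"control"}.
#' @return A [SectionStack-class].
#' @export
sectionStack <- function(sections, spacingUm = 300, subjectId = "",
                         organ = "", group = c("treated", "control")) {
  group <- match.arg(group)
  new("SectionStack", sections = sections, spacingUm = as.numeric(spacingUm),
      subjectId = as.character(subjectId), organ = as.character(organ),
      group = group)
}

setMethod("show", "SectionStack", function(object) {
  cat(sprintf("SectionStack: %d sections, %g um apart, group '%s'\n",
              length(object@sections), object@spacingUm, object@group))
  if (nzchar(object@subjectId)) cat("  subject:", object@subjectId, "\n")
  if (nzchar(object@organ)) cat("  organ:", object@organ, "\n")
})

#' Number of sections in a stack
#' @param x a [SectionStack-class].
#' @return integer.
#' @export
nSections <- function(x) length(x@sections)

#' Extract one section's channel pair
#' @param x a [SectionStack-class].
#' @param i section index.
#' @return \code{list(drug = IonImage, istd = IonImage)}.
#' @export
getSection <- function(x, i) x@sections[[i]]

#' Construct a PixelSpectra container
#'
#' @param coords integer matrix (n x 2) of 1-based (row, col) raster
#'   coordinates; duplicates are an error.
#' @param mz list of numeric m/z vectors, one per pixel.
#' @param intensity list of matching intensity vectors.
#' @param mzRange acquired m/z range, e.g. \code{c(250, 300)}.
#' @param pixelSizeUm pixel edge in micrometres.
#' @return A [PixelSpectra-class].
#' @export
pixelSpectra <- function(coords, mz, intensity, mzRange = c(250, 300),
                         pixelSizeUm = 100) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  new("PixelSpectra", coords = coords, mz = mz, intensity = intensity,
      mzRange = as.numeric(mzRange), pixelSizeUm = as.numeric(pixelSizeUm))
}

setMethod("show", "PixelSpectra", function(object) {
  cat(sprintf("PixelSpectra: %d pixels, m/z %g-%g, %g um/pixel\n",
              nrow(object@coords), object@mzRange[1L], object@mzRange[2L],
              object@pixelSizeUm))
})

#' Extract an ion image from per-pixel spectra
#'
#' Sums, for every acquired pixel, the spectral intensities whose m/z falls
#' in the closed window \code{[mz - tol, mz + tol]}. The output grid spans
#' the bounding box of the pixel coordinates; coordinates without a spectrum
#' are masked.
#'
#' @param spectra a [PixelSpectra-class].
#' @param mz window centre, e.g. 284.2 for the paclitaxel fragment.
#' @param tol window half-width in Da (default 0.25).
#' @param label label for the resulting image.
#' @return An [IonImage-class].
#' @examples
#' sp <- pixelSpectra(rbind(c(1, 1)), list(c(283.9, 284.2, 284.5, 289.2)),
#'                    list(c(5, 10, 3, 7)))
#' intensityValues(extractIonImage(sp, 284.2))[1, 1]  # 15
#' @export
extractIonImage <- function(spectra, mz, tol = 0.25, label = "") {
  stopifnot(is(spectra, "PixelSpectra"), tol > 0)
  lo <- mz - tol; hi <- mz + tol
  if (lo < spectra@mzRange[1L] || hi > spectra@mzRange[2L])
    stop(sprintf(
      "extraction window [%.4f, %.4f] lies outside the acquired m/z range [%g, %g]",
      lo, hi, spectra@mzRange[1L], spectra@mzRange[2L]))
  co <- spectra@coords
  r0 <- min(co[, 1L]); c0 <- min(co[, 2L])
  nr <- max(co[, 1L]) - r0 + 1L
  nc <- max(co[, 2L]) - c0 + 1L
  vals <- matrix(NA_real_, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(co))) {
    m <- spectra@mz[[i]]
    sel <- m >= lo & m <= hi
    vals[co[i, 1L] - r0 + 1L, co[i, 2L] - c0 + 1L] <-
      sum(spectra@intensity[[i]][sel])
    mask[co[i, 1L] - r0 + 1L, co[i, 2L] - c0 + 1L] <- TRUE
  }
  ionImage(vals, mask, pixelSizeUm = spectra@pixelSizeUm, targetMz = mz,
           mzTolerance = tol, label = label)
}

#' Construct a ROI from explicit pixel coordinates
#'
#' @param coords matrix (n x 2) of 1-based (row, col) coordinates.
#' @param pixelSizeUm pixel edge in micrometres.
#' @return A [ROI-class].
#' @export
pixelRoi <- function(coords, pixelSizeUm = 100) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("row", "col")
  new("ROI", coords = coords, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Circular ROI with an exact pixel count
#'
#' Returns the \code{nPixels} grid pixels nearest to \code{center}
#' (Euclidean distance between pixel centres), ties broken by (row, col)
#' lexicographic order. This construction guarantees the exact cardinality
#' that a rasterized radius cannot (e.g. the 25-pixel circular ROIs used for
#' zonal quantification).
#'
#' @param center numeric(2): (row, col) of the centre pixel.
#' @param nPixels target pixel count (>= 1).
#' @param gridShape integer(2): grid dimensions (nrow, ncol).
#' @param pixelSizeUm pixel edge in micrometres.
#' @return A [ROI-class] with exactly \code{nPixels} pixels.
#' @examples
#' roi <- makeCircularRoi(c(5, 5), 25, c(20, 20))
#' areaMm2(roi)  # 0.25 mm^2 at 100 um pixels
#' @export
makeCircularRoi <- function(center, nPixels, gridShape, pixelSizeUm = 100) {
  stopifnot(nPixels >= 1, length(gridShape) == 2L)
  if (prod(gridShape) < nPixels)
    stop(sprintf("grid has %d pixels, fewer than the requested %d",
                 prod(gridShape), nPixels))
  if (center[1L] < 1 || center[1L] > gridShape[1L] ||
      center[2L] < 1 || center[2L] > gridShape[2L])
    stop("center must lie inside the grid")
  rows <- rep(seq_len(gridShape[1L]), times = gridShape[2L])
  cols <- rep(seq_len(gridShape[2L]), each = gridShape[1L])
  d2 <- (rows - center[1L])^2 + (cols - center[2L])^2
  ord <- order(d2, rows, cols)[seq_len(nPixels)]
  pixelRoi(cbind(rows[ord], cols[ord]), pixelSizeUm = pixelSizeUm)
}

#' @rdname accessors
#' @export
setMethod("roiCoords", "ROI", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ROI", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("areaMm2", "ROI", function(x)
  nrow(x@coords) * (x@pixelSizeUm / 1000)^2)

#' @rdname accessors
#' @export
setMethod("nValidPixels", "ROI", function(x) nrow(x@coords))

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI: %d pixels, %.4g mm^2 (%g um/pixel)\n",
              nrow(object@coords), areaMm2(object), object@pixelSizeUm))
})

#' A ROI covering every valid pixel of an image
#'
#' Convenience for whole-section statistics (RSD, bulk quantification).
#'
#' @param image an [IonImage-class].
#' @return A [ROI-class] over all valid pixels.
#' @export
wholeSectionRoi <- function(image) {
  idx <- which(image@mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("image has no valid pixels")
  pixelRoi(idx, pixelSizeUm = image@pixelSizeUm)
}

#' Read / write ROI specifications as JSON
#'
#' The JSON interface accepts either
#' \code{\{"kind":"circle","center":[r,c],"n_pixels":25\}} or
#' \code{\{"kind":"pixels","coords":[[r,c], ...]\}} with 1-based (row, col)
#' coordinates.
#'
#' @param path JSON file path.
#' @param gridShape grid dimensions, required to realize circle specs.
#' @param pixelSizeUm pixel edge in micrometres.
#' @param roi a [ROI-class] (written as a \code{pixels} spec).
#' @return \code{readRoiJson} returns a [ROI-class]; \code{writeRoiJson}
#'   returns \code{path} invisibly.
#' @export
readRoiJson <- function(path, gridShape, pixelSizeUm = 100) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(spec$kind, "circle")) {
    makeCircularRoi(as.numeric(spec$center), as.integer(spec$n_pixels),
                    gridShape, pixelSizeUm = pixelSizeUm)
  } else if (identical(spec$kind, "pixels")) {
    pixelRoi(matrix(as.integer(spec$coords), ncol = 2L),
             pixelSizeUm = pixelSizeUm)
  } else {
    stop("unknown ROI kind: ", spec$kind %||% "<missing>")
  }
}

#' @rdname readRoiJson
#' @export
writeRoiJson <- function(roi, path) {
  co <- roi@coords
  dimnames(co) <- NULL
  jsonlite::write_json(list(kind = "pixels", coords = co), path,
                       auto_unbox = TRUE)
  invisible(path)
}
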