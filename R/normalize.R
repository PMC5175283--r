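#' Per-pixel internal-standard normalization
#'
#' Divides the drug ion image by the sprayed internal-standard ion image
#' pixel by pixel. Because the deuterated standard is deposited uniformly,
#' its local intensity reports the local ion suppression, and the ratio
#' cancels any multiplicative suppression field shared by the two channels.
#' Pixels whose internal-standard intensity falls below \code{istdFloor} are
#' masked instead of divided, keeping ratios finite.
#'
#' @param drug drug-channel [IonImage-class].
#' @param istd internal-standard-channel [IonImage-class]; must match the
#'   drug image in shape and pixel size.
#' @param istdFloor minimum internal-standard intensity accepted for
#'   division. Default: 5\% of the median valid internal-standard
#'   intensity.
#' @return A [NormalizedImage-class]. The number of pixels masked by the
#'   floor is in slot \code{nFloorMasked}.
#' @examples
#' d <- ionImage(matrix(c(2, 4, 6, 8), 2))
#' i <- ionImage(matrix(2, 2, 2))
#' intensityValues(normalizeIntensity(d, i))
#' @export
normalizeIntensity <- function(drug, istd, istdFloor = NULL) {
  stopifnot(is(drug, "IonImage"), is(istd, "IonImage"))
  if (!identical(dim(drug@values), dim(istd@values)))
    stop("drug and internal-standard images differ in shape")
  if (drug@pixelSizeUm != istd@pixelSizeUm)
    stop("drug and internal-standard images differ in pixel size")
  if (is.null(istdFloor)) {
    iv <- istd@values[istd@mask]
    if (length(iv) == 0L) stop("no valid internal-standard signal")
    istdFloor <- 0.05 * stats::median(iv)
  }
  if (istdFloor <= 0) stop("'istdFloor' must be > 0")
  common <- drug@mask & istd@mask
  ok <- common & !is.na(istd@values) & istd@values >= istdFloor
  if (!any(ok)) stop("no valid internal-standard signal")
  ratio <- matrix(NA_real_, nrow(drug@values), ncol(drug@values))
  ratio[ok] <- drug@values[ok] / istd@values[ok]
  new("NormalizedImage",
      values = ratio, mask = ok, pixelSizeUm = drug@pixelSizeUm,
      targetMz = drug@targetMz, mzTolerance = drug@mzTolerance,
      label = sprintf("%s / %s", drug@label, istd@label),
      istdFloor = as.numeric(istdFloor),
      provenance = c(drug = drug@label, istd = istd@label),
      nFloorMasked = as.integer(sum(common & !ok)))
}

setMethod("show", "NormalizedImage", function(object) {
  callNextMethod()
  cat(sprintf("  istd floor: %.4g (%d pixels floor-masked)\n",
              object@istdFloor, object@nFloorMasked))
})

#' Relative standard deviation (RSD\%) over a ROI
#'
#' \code{100 * sd / mean} of the valid pixel values in a ROI, with the
#' sample (n - 1) standard deviation. Used to quantify pixel-level
#' variability of the raw drug signal and the benefit of normalization.
#'
#' @param image an [IonImage-class] or [NormalizedImage-class].
#' @param roi a [ROI-class], or \code{NULL} for the whole section.
#' @return RSD as a percentage.
#' @examples
#' img <- ionImage(matrix(c(1, 3), 1))
#' rsdPercent(img)  # 100 * sqrt(2) / 2
#' @export
rsdPercent <- function(image, roi = NULL) {
  v <- roiValues(image, roi)
  if (length(v) < 2L) stop("RSD requires >= 2 valid pixels")
  m <- mean(v)
  if (m <= 0) stop("RSD undefined: mean of ROI values is <= 0")
  100 * stats::sd(v) / m
}

#' Raw-versus-normalized RSD report for one ROI
#'
#' Computes both RSD\% values over the identical pixel set (the valid mask
#' of the normalized image intersected with the ROI), so the comparison is
#' not confounded by differing masks.
#'
#' @param drug,istd the two channel [IonImage-class]s.
#' @param roi a [ROI-class], or \code{NULL} for the whole section.
#' @param istdFloor passed to [normalizeIntensity()].
#' @param label ROI label for the report row.
#' @return A one-row data.frame with columns \code{label}, \code{rsd_raw},
#'   \code{rsd_norm}, \code{n_pixels} (CSV-ready).
#' @export
rsdReport <- function(drug, istd, roi = NULL, istdFloor = NULL,
                      label = "whole_section") {
  norm <- normalizeIntensity(drug, istd, istdFloor)
  rawOnCommon <- ionImage(drug@values, mask = norm@mask,
                          pixelSizeUm = drug@pixelSizeUm)
  data.frame(
    label = label,
    rsd_raw = rsdPercent(rawOnCommon, roi),
    rsd_norm = rsdPercent(norm, roi),
    n_pixels = length(roiValues(norm, roi)),
    stringsAsFactors = FALSE)
}

#' Compare two serial-section series
#'
#' For each section of each stack, computes the whole-section mean
#' drug/internal-standard ratio and mean internal-standard intensity, then
#' compares the two stacks with Welch's two-sided t-test on each quantity.
#' Used to check that two series of sections from the same specimen are
#' statistically indistinguishable.
#'
#' @param stackA,stackB [SectionStack-class]s with >= 2 sections each.
#' @param istdFloor passed to [normalizeIntensity()].
#' @return A list with elements \code{perSection} (data.frame: series,
#'   section, meanRatio, meanIstd), \code{ratioTest} and \code{istdTest}
#'   (each \code{list(t, p, meanA, meanB)}).
#' @export
compareSeries <- function(stackA, stackB, istdFloor = NULL) {
  if (nSections(stackA) < 2L || nSections(stackB) < 2L)
    stop("each stack must contain >= 2 sections")
  sectionMeans <- function(stack, tag) {
    do.call(rbind, lapply(seq_len(nSections(stack)), function(i) {
      s <- getSection(stack, i)
      norm <- normalizeIntensity(s$drug, s$istd, istdFloor)
      data.frame(series = tag, section = i,
                 meanRatio = mean(norm@values[norm@mask]),
                 meanIstd = mean(s$istd@values[s$istd@mask]),
                 stringsAsFactors = FALSE)
    }))
  }
  per <- rbind(sectionMeans(stackA, "A"), sectionMeans(stackB, "B"))
  welch <- function(col) {
    a <- per[per$series == "A", col]; b <- per[per$series == "B", col]
    if (stats::sd(c(a, b)) == 0)
      stop("degenerate series comparison: zero variance in per-section ",
           col)
    tt <- stats::t.test(a, b)
    list(t = unname(tt$statistic), p = unname(tt$p.value),
         meanA = mean(a), meanB = mean(b))
  }
  list(perSection = per,
       ratioTest = welch("meanRatio"),
       istdTest = welch("meanIstd"))
}
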