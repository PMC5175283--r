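#' Estimate the background positivity threshold from untreated controls
#'
#' Pools the valid (normalized) pixel values of untreated control sections —
#' optionally restricted to ROIs — and derives the positivity cutoff
#' \code{threshold = mean + k * sd}. A pixel of a treated section counts as
#' drug-positive when its value strictly exceeds this cutoff, i.e. when the
#' signal change is greater than the background noise of untreated tissue.
#'
#' @param controlImages a [NormalizedImage-class]/[IonImage-class] or a
#'   list of them.
#' @param rois optional list of [ROI-class] (parallel to
#'   \code{controlImages}) restricting the pooled pixels.
#' @param k standard-deviation multiplier (default 3).
#' @return A [ThresholdModel-class].
#' @export
estimateThreshold <- function(controlImages, rois = NULL, k = 3) {
  if (is(controlImages, "IonImage")) controlImages <- list(controlImages)
  if (!is.null(rois) && !is.list(rois)) rois <- list(rois)
  vals <- unlist(lapply(seq_along(controlImages), function(i)
    roiValues(controlImages[[i]],
              if (is.null(rois)) NULL else rois[[i]])))
  if (length(vals) < 2L)
    stop("no (or too few) control pixels to estimate a background threshold")
  m <- mean(vals); s <- stats::sd(vals)
  new("ThresholdModel", meanBg = m, sdBg = s, k = as.numeric(k),
      threshold = m + k * s, nControlPixels = length(vals))
}

#' @rdname accessors
#' @export
setMethod("thresholdValue", "ThresholdModel", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("thresholdValue", "numeric", function(x) x)

setMethod("show", "ThresholdModel", function(object) {
  cat(sprintf(
    "ThresholdModel: threshold = %.4g (mean %.4g + %g sd %.4g; %d control pixels)\n",
    object@threshold, object@meanBg, object@k, object@sdBg,
    object@nControlPixels))
})

#' Percent of drug-positive pixels in a ROI
#'
#' \code{100 * #\{valid pixels > threshold\} / #\{valid pixels\}}; the
#' inequality is strict, so ties at the threshold count as negative.
#'
#' @param image a [NormalizedImage-class] (or [IonImage-class]).
#' @param threshold numeric cutoff or a [ThresholdModel-class].
#' @param roi a [ROI-class], or \code{NULL} for the whole section.
#' @return percentage in [0, 100].
#' @examples
#' img <- ionImage(matrix(0:3, 2))
#' percentPositive(img, 1.5)  # 50
#' @export
percentPositive <- function(image, threshold, roi = NULL) {
  thr <- thresholdValue(threshold)
  v <- roiValues(image, roi)
  if (length(v) == 0L) stop("ROI contains no valid pixels")
  100 * sum(v > thr) / length(v)
}

# Connected-component labeling of a binary mask by iterative minimum-label
# propagation: each positive pixel starts with a unique id and repeatedly
# takes the minimum id among itself and its (4- or 8-) neighbours until a
# fixed point. Labels are then canonicalized to 1..n in order of each
# component's smallest linear index.
labelComponents <- function(bin, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(bin); nc <- ncol(bin)
  npos <- sum(bin)
  if (npos == 0L) return(list(labels = matrix(0L, nr, nc), n = 0L))
  lab <- matrix(0, nr, nc)
  lab[bin] <- seq_len(npos)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  big <- npos + 1
  repeat {
    cur <- lab
    cur[!bin] <- big
    best <- cur
    for (o in offs) {
      nb <- shiftMat(cur, o[1L], o[2L], fill = big)
      best <- pmin(best, nb)
    }
    best[!bin] <- 0
    if (identical(best, lab)) break
    lab <- best
  }
  ids <- sort(unique(lab[lab > 0]))
  canon <- match(lab, ids)
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- canon[lab > 0]
  # renumber by first (column-major) occurrence for determinism
  firsts <- vapply(seq_along(ids), function(i) which(out == i)[1L],
                   numeric(1L))
  remap <- match(seq_along(ids), order(firsts))
  out[out > 0] <- remap[out[out > 0]]
  storage.mode(out) <- "integer"
  list(labels = out, n = length(ids))
}

#' Particle analysis of drug-positive pixel clusters
#'
#' Thresholds the image (strict exceedance), labels connected components of
#' positive pixels ("particles") and measures each one: size in pixels and
#' mm2, perimeter as the count of exposed 4-neighbourhood pixel edges
#' converted to mm, and circularity \code{min(1, 4*pi*area/perimeter^2)}
#' computed in consistent units (capped at 1, as in ImageJ).
#'
#' @param image a [NormalizedImage-class] (or [IonImage-class]).
#' @param threshold numeric cutoff or [ThresholdModel-class].
#' @param connectivity 8 (default; diagonal neighbours join a cluster) or 4.
#' @return A [ParticleStats-class]; zero particles gives an empty table.
#' @examples
#' m <- matrix(0, 5, 5); m[2:3, 2:3] <- 1
#' particleTable(particleAnalysis(ionImage(m), 0.5))
#' @export
particleAnalysis <- function(image, threshold, connectivity = 8) {
  thr <- thresholdValue(threshold)
  bin <- image@mask & !is.na(image@values) & image@values > thr
  lab <- labelComponents(bin, connectivity)
  pxMm <- image@pixelSizeUm / 1000
  if (lab$n == 0L) {
    tab <- data.frame(id = integer(0), sizePx = integer(0),
                      sizeMm2 = numeric(0), perimeterEdges = integer(0),
                      perimeterMm = numeric(0), circularity = numeric(0))
    return(new("ParticleStats", particles = tab,
               connectivity = as.integer(connectivity),
               pixelSizeUm = image@pixelSizeUm))
  }
  sizes <- tabulate(lab$labels[lab$labels > 0], nbins = lab$n)
  # exposed edges: positive pixel faces a non-positive 4-neighbour or the
  # grid border
  edges <- numeric(lab$n)
  for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- shiftMat(bin, o[1L], o[2L], fill = FALSE)
    exposed <- bin & !nb
    tal <- tabulate(lab$labels[exposed], nbins = lab$n)
    edges <- edges + tal
  }
  tab <- data.frame(
    id = seq_len(lab$n),
    sizePx = sizes,
    sizeMm2 = sizes * pxMm^2,
    perimeterEdges = as.integer(edges),
    perimeterMm = edges * pxMm,
    circularity = pmin(1, 4 * pi * sizes / edges^2))
  new("ParticleStats", particles = tab,
      connectivity = as.integer(connectivity),
      pixelSizeUm = image@pixelSizeUm)
}

#' @rdname accessors
#' @export
setMethod("particleTable", "ParticleStats", function(x) x@particles)

#' Summary statistics of a particle analysis
#'
#' @param stats a [ParticleStats-class].
#' @return list with \code{nParticles}, \code{meanSizePx},
#'   \code{meanSizeMm2}, \code{meanPerimeterMm}, \code{meanCircularity}
#'   (means are \code{NA} with zero particles).
#' @export
particleSummary <- function(stats) {
  p <- stats@particles
  n <- nrow(p)
  list(nParticles = n,
       meanSizePx = if (n) mean(p$sizePx) else NA_real_,
       meanSizeMm2 = if (n) mean(p$sizeMm2) else NA_real_,
       meanPerimeterMm = if (n) mean(p$perimeterMm) else NA_real_,
       meanCircularity = if (n) mean(p$circularity) else NA_real_)
}

setMethod("show", "ParticleStats", function(object) {
  s <- particleSummary(object)
  cat(sprintf(
    "ParticleStats: %d particles (%d-connectivity)\n", s$nParticles,
    object@connectivity))
  if (s$nParticles > 0)
    cat(sprintf(
      "  mean size %.3g px (%.4g mm^2), mean perimeter %.4g mm, mean circularity %.3f\n",
      s$meanSizePx, s$meanSizeMm2, s$meanPerimeterMm, s$meanCircularity))
})

#' Heterogeneity report for one section
#'
#' Bundles the percent-positive metric and the particle statistics of a
#' normalized section at a given background threshold.
#'
#' @param image a [NormalizedImage-class].
#' @param threshold numeric or [ThresholdModel-class].
#' @param roi ROI enclosing the analysed region (default: whole section).
#' @param connectivity particle connectivity (8 or 4).
#' @param label section label.
#' @return list with \code{label}, \code{percentPositive}, \code{threshold},
#'   \code{particles} ([ParticleStats-class]), \code{nRoiPixels}.
#' @export
heterogeneityReport <- function(image, threshold, roi = NULL,
                                connectivity = 8, label = "") {
  thr <- thresholdValue(threshold)
  list(label = label,
       percentPositive = percentPositive(image, thr, roi),
       threshold = thr,
       particles = particleAnalysis(image, thr, connectivity),
       nRoiPixels = length(roiValues(image, roi)))
}

#' Export the binary positive-pixel mask as a PNG
#'
#' @param image a [NormalizedImage-class] (or [IonImage-class]).
#' @param threshold numeric or [ThresholdModel-class].
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMaskPng <- function(image, threshold, path) {
  thr <- thresholdValue(threshold)
  bin <- image@mask & !is.na(image@values) & image@values > thr
  png::writePNG(matrix(as.numeric(bin), nrow(bin), ncol(bin)), path)
  invisible(path)
}
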