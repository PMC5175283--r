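# Synthetic tumor-section phantoms with ground truth.
#
# Forward model per pixel:
#   drug  = gain * density * s * noise_d + background
#   istd  = istdNominal   * s * noise_i + background
# where s is a spatially smooth multiplicative ion-suppression field shared
# by both channels (the physics the internal-standard ratio is designed to
# cancel), noise_* are independent unit-mean lognormal factors and the
# background is Gaussian truncated at zero. Densities are in pmol/mm2,
# intensities in arbitrary ion counts.

#' Smooth ion-suppression field
#'
#' Low-pass-filtered seeded white noise, min-max rescaled to
#' \code{[sMin, sMax]} (the output attains both bounds exactly). The
#' correlation length sets the Gaussian smoothing scale in pixels.
#'
#' @param shape integer(2) grid dimensions.
#' @param correlationLengthPx smoothing scale in pixels (> 0).
#' @param sMin,sMax field bounds, \code{0 < sMin <= sMax}; equal bounds give
#'   a constant field.
#' @param seed RNG seed.
#' @return numeric matrix in \code{[sMin, sMax]}.
#' @export
makeSuppressionField <- function(shape, correlationLengthPx = 8,
                                 sMin = 0.4, sMax = 1.0, seed = 1) {
  if (sMin <= 0 || sMax < sMin) stop("need 0 < sMin <= sMax")
  if (correlationLengthPx <= 0) stop("correlationLengthPx must be > 0")
  withSeed(seed, {
    raw <- matrix(stats::rnorm(prod(shape)), shape[1L], shape[2L])
    f <- gaussianSmooth(raw, correlationLengthPx)
    rng <- range(f)
    if (sMax == sMin || rng[2L] == rng[1L]) {
      matrix(sMin, shape[1L], shape[2L])
    } else {
      (f - rng[1L]) / (rng[2L] - rng[1L]) * (sMax - sMin) + sMin
    }
  })
}

#' Phantom configuration
#'
#' Collects every knob of the phantom generator with defaults emulating the
#' acquisition this package targets: 100-um raster, a 60 x 60 grid
#' (6 x 6 mm section), viable-tissue drug density of 5 pmol/mm2 (mid
#' calibration range), internal standard sprayed at nominal intensity 1000
#' counts, suppression between 0.4 and 1.0 with ~0.8 mm correlation length,
#' 5\% multiplicative channel noise, a small truncated-Gaussian background,
#' and three serial sections with jittered compartment boundaries.
#'
#' Archetypes: \code{homogeneous} (uniform drug), \code{necrotic_core}
#' (central drug-free core), \code{patchy_vascular} (drug decaying
#' exponentially around seeded vessel points), \code{fibrotic} (drug-free
#' lamellae), \code{scant} (drug restricted to sparse patches).
#'
#' @param gridShape integer(2) grid dimensions.
#' @param pixelSizeUm pixel edge (um).
#' @param archetype one of the five archetypes above.
#' @param viableDensity drug density in drug-bearing tissue (pmol/mm2).
#' @param coreFraction fraction of tissue taken by the necrotic core.
#' @param fibroticFraction fraction of tissue taken by fibrotic lamellae.
#' @param supportFraction fraction of tissue bearing drug in \code{scant}.
#' @param nVessels vessel seed count for \code{patchy_vascular}.
#' @param decayLengthUm exponential penetration decay length from vessels.
#' @param patchyCutoff density (as a fraction of \code{viableDensity})
#'   below which the vascular decay is truncated to zero.
#' @param sMin,sMax,correlationLengthPx suppression-field spec.
#' @param istdNominal sprayed internal-standard nominal intensity (counts).
#' @param gain detector gain, counts per (pmol/mm2).
#' @param sprayNoiseCv,detectorNoiseCv multiplicative noise CVs of the
#'   internal-standard and drug channels.
#' @param bgScale background scale: the additive background is Gaussian
#'   with sd \code{bgScale} and mean \code{10 * bgScale}, truncated at 0.
#' @param nSections serial sections per phantom.
#' @param spacingUm section spacing (um).
#' @param jitterPx sd of the compartment-boundary jitter between sections.
#' @param seed RNG seed; fixed seed means fully reproducible output.
#' @return A list of class \code{"phantomConfig"}.
#' @seealso [makePhantom()]
#' @export
phantomConfig <- function(gridShape = c(60, 60), pixelSizeUm = 100,
                          archetype = c("homogeneous", "necrotic_core",
                                        "patchy_vascular", "fibrotic",
                                        "scant"),
                          viableDensity = 5,
                          coreFraction = 0.35, fibroticFraction = 0.4,
                          supportFraction = 0.35,
                          nVessels = 25, decayLengthUm = 300,
                          patchyCutoff = 0.1,
                          sMin = 0.4, sMax = 1.0, correlationLengthPx = 8,
                          istdNominal = 1000, gain = 100,
                          sprayNoiseCv = 0.05, detectorNoiseCv = 0.05,
                          bgScale = 0.5, nSections = 3, spacingUm = 300,
                          jitterPx = 1, seed = 1) {
  archetype <- match.arg(archetype)
  cfg <- as.list(environment())
  if (any(c(coreFraction, fibroticFraction, supportFraction) < 0) ||
      any(c(coreFraction, fibroticFraction, supportFraction) > 1))
    stop("compartment fractions must lie in [0, 1]")
  if (sMin <= 0) stop("sMin must be > 0")
  if (sprayNoiseCv < 0 || detectorNoiseCv < 0 || bgScale < 0)
    stop("noise parameters must be >= 0")
  structure(cfg, class = "phantomConfig")
}

# Elliptical tissue mask with smoothly wobbled radius.
tissueEllipse <- function(shape, center, semi, wobbleAmp = 0.05,
                          fourier = NULL) {
  r <- row(matrix(0, shape[1L], shape[2L])) - center[1L]
  c_ <- col(matrix(0, shape[1L], shape[2L])) - center[2L]
  theta <- atan2(c_ / semi[2L], r / semi[1L])
  rad <- sqrt((r / semi[1L])^2 + (c_ / semi[2L])^2)
  if (is.null(fourier)) fourier <- stats::rnorm(4, sd = wobbleAmp)
  mod <- 1 + fourier[1L] * cos(theta) + fourier[2L] * sin(theta) +
    fourier[3L] * cos(2 * theta) + fourier[4L] * sin(2 * theta)
  rad <= mod
}

# Density + compartment maps for one section of a given archetype.
# All randomness is drawn from the current stream.
drawCompartments <- function(cfg, tissue, center) {
  shape <- cfg$gridShape
  density <- matrix(0, shape[1L], shape[2L])
  comp <- matrix("off", shape[1L], shape[2L])
  comp[tissue] <- "viable"
  density[tissue] <- cfg$viableDensity
  if (cfg$archetype == "necrotic_core") {
    core <- tissueEllipse(shape,
                          center + stats::rnorm(2, sd = cfg$jitterPx),
                          sqrt(cfg$coreFraction) * 0.45 * shape,
                          wobbleAmp = 0.08)
    core <- core & tissue
    comp[core] <- "necrotic"
    density[core] <- 0
  } else if (cfg$archetype == "fibrotic") {
    angle <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    period <- 12
    proj <- row(density) * cos(angle) + col(density) * sin(angle)
    wave <- sin(2 * pi * proj / period + phase)
    cut <- stats::quantile(wave[tissue], 1 - cfg$fibroticFraction,
                           names = FALSE)
    lam <- tissue & wave > cut
    comp[lam] <- "fibrotic"
    density[lam] <- 0
  } else if (cfg$archetype == "scant") {
    field <- gaussianSmooth(matrix(stats::rnorm(prod(shape)), shape[1L]), 5)
    cut <- stats::quantile(field[tissue], 1 - cfg$supportFraction,
                           names = FALSE)
    none <- tissue & field <= cut
    comp[none] <- "none"
    density[none] <- 0
  } else if (cfg$archetype == "patchy_vascular") {
    idx <- which(tissue)
    vs <- idx[sample.int(length(idx), min(cfg$nVessels, length(idx)))]
    vr <- (vs - 1L) %% shape[1L] + 1L
    vc <- (vs - 1L) %/% shape[1L] + 1L
    rr <- row(density); cc <- col(density)
    dmin <- matrix(Inf, shape[1L], shape[2L])
    for (j in seq_along(vr)) {
      d <- sqrt((rr - vr[j])^2 + (cc - vc[j])^2)
      dmin <- pmin(dmin, d)
    }
    decayPx <- cfg$decayLengthUm / cfg$pixelSizeUm
    dens <- cfg$viableDensity * exp(-dmin / decayPx)
    dens[dens < cfg$patchyCutoff * cfg$viableDensity] <- 0
    density[tissue] <- dens[tissue]
    comp[tissue & density == 0] <- "none"
  }
  list(density = density, comp = comp)
}

# Observe one section given its truth; draws noise from the current stream.
observeSection <- function(cfg, density, tissue, s, sectionLabel) {
  n <- prod(cfg$gridShape)
  bgMean <- 10 * cfg$bgScale
  drugVals <- cfg$gain * density * s *
    matrix(lnNoise(n, cfg$detectorNoiseCv), cfg$gridShape[1L]) +
    matrix(bgNoise(n, bgMean, cfg$bgScale), cfg$gridShape[1L])
  istdVals <- cfg$istdNominal * s *
    matrix(lnNoise(n, cfg$sprayNoiseCv), cfg$gridShape[1L]) +
    matrix(bgNoise(n, bgMean, cfg$bgScale), cfg$gridShape[1L])
  list(
    drug = ionImage(drugVals, mask = tissue,
                    pixelSizeUm = cfg$pixelSizeUm, targetMz = 284.2,
                    mzTolerance = 0.25,
                    label = paste0(sectionLabel, ":drug")),
    istd = ionImage(istdVals, mask = tissue,
                    pixelSizeUm = cfg$pixelSizeUm, targetMz = 289.2,
                    mzTolerance = 0.25,
                    label = paste0(sectionLabel, ":istd")))
}

#' Generate a phantom section stack with ground truth
#'
#' Draws the compartment geometry of the configured archetype, a fresh
#' suppression field per section, and observes both channels through the
#' forward model. Serial sections are jittered re-draws of the compartment
#' boundaries, emulating non-adjacent sections of one specimen.
#'
#' @param config a [phantomConfig()] list.
#' @return list with \code{stack} (a [SectionStack-class], group
#'   \code{"treated"}) and \code{truth} (list of [PhantomTruth-class], one
#'   per section).
#' @examples
#' ph <- makePhantom(phantomConfig(gridShape = c(24, 24), nSections = 1,
#'                                 seed = 7))
#' ph$truth[[1]]@positiveSupportFraction
#' @export
makePhantom <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  cfg <- config
  withSeed(cfg$seed, {
    baseCenter <- (cfg$gridShape + 1) / 2
    baseFourier <- stats::rnorm(4, sd = 0.05)
    sections <- vector("list", cfg$nSections)
    truth <- vector("list", cfg$nSections)
    for (i in seq_len(cfg$nSections)) {
      center <- baseCenter + stats::rnorm(2, sd = cfg$jitterPx)
      tissue <- tissueEllipse(cfg$gridShape, center, 0.45 * cfg$gridShape,
                              fourier = baseFourier +
                                stats::rnorm(4, sd = 0.01))
      cm <- drawCompartments(cfg, tissue, center)
      s <- makeSuppressionField(cfg$gridShape, cfg$correlationLengthPx,
                                cfg$sMin, cfg$sMax,
                                seed = stats::runif(1, 1, 2^30))
      sections[[i]] <- observeSection(cfg, cm$density, tissue, s,
                                      sprintf("%s_s%d", cfg$archetype, i))
      dm <- cm$density
      dm[!tissue] <- NA_real_
      truth[[i]] <- new("PhantomTruth", densityMap = dm,
                        compartmentMap = cm$comp, suppressionField = s,
                        positiveSupportFraction =
                          mean(cm$density[tissue] > 0),
                        zoneDensities = numeric(0))
    }
    list(stack = sectionStack(sections, spacingUm = cfg$spacingUm,
                              subjectId = sprintf("phantom_seed%g",
                                                  cfg$seed),
                              organ = "tumor", group = "treated"),
         truth = truth)
  })
}

#' Designed-contrast phantom with three density plateaus
#'
#' A tissue section whose drug density takes three exactly known plateau
#' values in three bands, so the high/mid/low zonation and the fold-ratio
#' recovery can be checked against ground truth. Default plateau densities
#' are in the ratios 1 : 1/2.09 : 1/4.76, placing the mid and low plateaus
#' at about 48\% and 21\% of the section maximum — inside the mid
#' (25-75\%) and low (<25\%) zones.
#'
#' @param densities named numeric: plateau densities (pmol/mm2) for
#'   \code{high}, \code{mid}, \code{low}.
#' @param config a [phantomConfig()]; its archetype is ignored.
#' @return As [makePhantom()]; each truth carries \code{zoneDensities}.
#' @export
makeZonedPhantom <- function(config,
                             densities = c(high = 5, mid = 5 / 2.09,
                                           low = 5 / 4.76)) {
  stopifnot(inherits(config, "phantomConfig"),
            all(c("high", "mid", "low") %in% names(densities)))
  cfg <- config
  withSeed(cfg$seed, {
    baseCenter <- (cfg$gridShape + 1) / 2
    sections <- vector("list", cfg$nSections)
    truth <- vector("list", cfg$nSections)
    for (i in seq_len(cfg$nSections)) {
      center <- baseCenter + stats::rnorm(2, sd = cfg$jitterPx)
      tissue <- tissueEllipse(cfg$gridShape, center, 0.45 * cfg$gridShape,
                              wobbleAmp = 0.03)
      rows <- row(matrix(0, cfg$gridShape[1L], cfg$gridShape[2L]))
      tr <- range(which(apply(tissue, 1L, any)))
      b1 <- tr[1L] + floor(diff(tr) / 3)
      b2 <- tr[1L] + floor(2 * diff(tr) / 3)
      density <- matrix(0, cfg$gridShape[1L], cfg$gridShape[2L])
      density[tissue & rows <= b1] <- densities[["high"]]
      density[tissue & rows > b1 & rows <= b2] <- densities[["mid"]]
      density[tissue & rows > b2] <- densities[["low"]]
      comp <- matrix("off", cfg$gridShape[1L], cfg$gridShape[2L])
      comp[tissue] <- "viable"
      s <- makeSuppressionField(cfg$gridShape, cfg$correlationLengthPx,
                                cfg$sMin, cfg$sMax,
                                seed = stats::runif(1, 1, 2^30))
      sections[[i]] <- observeSection(cfg, density, tissue, s,
                                      sprintf("zoned_s%d", i))
      dm <- density
      dm[!tissue] <- NA_real_
      truth[[i]] <- new("PhantomTruth", densityMap = dm,
                        compartmentMap = comp, suppressionField = s,
                        positiveSupportFraction = mean(density[tissue] > 0),
                        zoneDensities = densities)
    }
    list(stack = sectionStack(sections, spacingUm = cfg$spacingUm,
                              subjectId = sprintf("zoned_seed%g", cfg$seed),
                              organ = "tumor", group = "treated"),
         truth = truth)
  })
}

#' Generate a calibration section with spotted drug amounts
#'
#' Renders circular calibration spots of known amounts (default six levels
#' spanning 0.2-15 pmol on 25-pixel spots, i.e. 0.8-60 pmol/mm2) on a
#' control-tissue grid. Each spot receives its own ion-suppression factor
#' drawn uniformly from \code{sRange}, which degrades the raw calibration
#' line and is cancelled by internal-standard normalization.
#'
#' @param amountsPmol distinct positive spotted amounts (pmol).
#' @param spotPixels pixels per spot ROI.
#' @param sRange per-spot suppression factor range (uniform draw).
#' @param noiseCv per-pixel multiplicative noise CV (both channels).
#' @param gain,istdNominal,bgScale,pixelSizeUm forward-model parameters as
#'   in [phantomConfig()].
#' @param spacingPx empty pixels between spot bounding circles.
#' @param seed RNG seed.
#' @return list with \code{drug}, \code{istd} ([IonImage-class]s) and
#'   \code{spots} (list of [CalibrationSpot-class]).
#' @export
makeCalibrationSection <- function(amountsPmol = c(0.2, 0.5, 1.5, 5, 10, 15),
                                   spotPixels = 25, sRange = c(0.4, 1.0),
                                   noiseCv = 0.01, gain = 100,
                                   istdNominal = 1000, bgScale = 0.5,
                                   pixelSizeUm = 100, spacingPx = 3,
                                   seed = 1) {
  if (any(amountsPmol <= 0)) stop("spotted amounts must be positive")
  if (anyDuplicated(amountsPmol)) stop("spotted amounts must be distinct")
  n <- length(amountsPmol)
  rpx <- ceiling(sqrt(spotPixels / pi))
  step <- 2L * rpx + as.integer(spacingPx)
  shape <- c(2L * rpx + 7L, n * step + 7L)
  centers <- cbind(rep(rpx + 4L, n),
                   rpx + 4L + step * (seq_len(n) - 1L))
  rois <- lapply(seq_len(n), function(j)
    makeCircularRoi(centers[j, ], spotPixels, shape,
                    pixelSizeUm = pixelSizeUm))
  keys <- unlist(lapply(rois, function(r)
    paste(r@coords[, 1L], r@coords[, 2L])))
  if (anyDuplicated(keys)) stop("calibration spots overlap")
  withSeed(seed, {
    s <- matrix(1, shape[1L], shape[2L])
    u <- stats::runif(n, sRange[1L], sRange[2L])
    for (j in seq_len(n)) s[rois[[j]]@coords] <- u[j]
    density <- matrix(0, shape[1L], shape[2L])
    areaMm2Spot <- spotPixels * (pixelSizeUm / 1000)^2
    for (j in seq_len(n))
      density[rois[[j]]@coords] <- amountsPmol[j] / areaMm2Spot
    np <- prod(shape)
    bgMean <- 10 * bgScale
    drug <- gain * density * s * matrix(lnNoise(np, noiseCv), shape[1L]) +
      matrix(bgNoise(np, bgMean, bgScale), shape[1L])
    istd <- istdNominal * s * matrix(lnNoise(np, noiseCv), shape[1L]) +
      matrix(bgNoise(np, bgMean, bgScale), shape[1L])
    list(
      drug = ionImage(drug, pixelSizeUm = pixelSizeUm, targetMz = 284.2,
                      mzTolerance = 0.25, label = "calibration:drug"),
      istd = ionImage(istd, pixelSizeUm = pixelSizeUm, targetMz = 289.2,
                      mzTolerance = 0.25, label = "calibration:istd"),
      spots = lapply(seq_len(n), function(j)
        calibrationSpot(rois[[j]], amountsPmol[j])))
  })
}

#' Generate an untreated control section
#'
#' The drug channel holds only additive background (Gaussian with mean
#' \code{10 * bgScale} and sd \code{bgScale}, truncated at 0 — effectively
#' Gaussian); the internal-standard channel is sprayed as in treated
#' sections. Used to estimate the background positivity threshold. Pass the
#' treated phantom's suppression range for threshold estimation matched to
#' those sections, or keep the constant default for a homogeneous control
#' tissue.
#'
#' @param shape grid dimensions.
#' @param bgScale background scale (sd; 0 gives an all-zero drug channel).
#' @param istdNominal,istdNoiseCv internal-standard spray spec.
#' @param sMin,sMax,correlationLengthPx suppression-field spec (constant
#'   0.7 by default).
#' @param pixelSizeUm pixel edge (um).
#' @param seed RNG seed.
#' @return list with \code{drug} and \code{istd} [IonImage-class]s.
#' @export
makeControlSection <- function(shape = c(60, 60), bgScale = 0.5,
                               istdNominal = 1000, istdNoiseCv = 0.01,
                               sMin = 0.7, sMax = 0.7,
                               correlationLengthPx = 8, pixelSizeUm = 100,
                               seed = 1) {
  if (bgScale < 0) stop("bgScale must be >= 0")
  withSeed(seed, {
    s <- makeSuppressionField(shape, correlationLengthPx, sMin, sMax,
                              seed = stats::runif(1, 1, 2^30))
    np <- prod(shape)
    drug <- matrix(bgNoise(np, 10 * bgScale, bgScale), shape[1L])
    istd <- istdNominal * s * matrix(lnNoise(np, istdNoiseCv), shape[1L]) +
      matrix(bgNoise(np, 10 * bgScale, bgScale), shape[1L])
    list(
      drug = ionImage(drug, pixelSizeUm = pixelSizeUm, targetMz = 284.2,
                      mzTolerance = 0.25, label = "control:drug"),
      istd = ionImage(istd, pixelSizeUm = pixelSizeUm, targetMz = 289.2,
                      mzTolerance = 0.25, label = "control:istd"))
  })
}

#' Emit two-peak spectra for a phantom section
#'
#' Optional spectral mode: encodes a (drug, istd) image pair as per-pixel
#' two-peak spectra at m/z 284.2 and 289.2, for exercising
#' [extractIonImage()] and imzML round trips on realistic inputs.
#'
#' @param drug,istd the two channel [IonImage-class]s (shared mask).
#' @param mzRange acquired m/z range.
#' @return A [PixelSpectra-class].
#' @export
phantomSpectra <- function(drug, istd, mzRange = c(250, 300)) {
  stopifnot(identical(dim(drug@values), dim(istd@values)))
  idx <- which(drug@mask & istd@mask, arr.ind = TRUE)
  pixelSpectra(
    coords = idx,
    mz = rep(list(c(284.2, 289.2)), nrow(idx)),
    intensity = lapply(seq_len(nrow(idx)), function(i)
      c(drug@values[idx[i, , drop = FALSE]],
        istd@values[idx[i, , drop = FALSE]])),
    mzRange = mzRange, pixelSizeUm = drug@pixelSizeUm)
}
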