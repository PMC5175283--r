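#' Pipeline run configuration
#'
#' Assembles every stage parameter of [runPipeline()] into one validated
#' list: the simulation spec (archetypes, sections, phantom parameters),
#' the calibration and control specs, the threshold multiplier, zone
#' boundaries, ROI sampling parameters, particle connectivity, seeds and
#' the output directory. All seeds are recorded in every output for
#' provenance.
#'
#' @param archetypes phantom archetypes to simulate, one group each.
#' @param nSections sections per archetype.
#' @param gridShape phantom grid dimensions.
#' @param thresholdK background-threshold multiplier k.
#' @param fHigh,fLow zone boundaries (fractions of section max).
#' @param nPerZone,roiPixels,purity zone ROI sampling parameters.
#' @param connectivity particle connectivity (8 or 4).
#' @param calibrationAmounts spotted amounts (pmol) for the calibration
#'   section.
#' @param nControls untreated control sections for thresholding.
#' @param seed master seed; stage seeds are derived from it.
#' @param outputDir directory for report files (created if needed).
#' @param phantomArgs named list of extra arguments passed to
#'   [phantomConfig()] (noise, suppression, densities ...).
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(archetypes = c("homogeneous", "necrotic_core",
                                          "patchy_vascular"),
                           nSections = 3, gridShape = c(60, 60),
                           thresholdK = 3, fHigh = 0.75, fLow = 0.25,
                           nPerZone = 3, roiPixels = 25, purity = 0.8,
                           connectivity = 8,
                           calibrationAmounts = c(0.2, 0.5, 1.5, 5, 10, 15),
                           nControls = 9, seed = 1,
                           outputDir = tempfile("msihet_run"),
                           phantomArgs = list()) {
  stopifnot(length(archetypes) >= 1L, nSections >= 1L,
            connectivity %in% c(4, 8))
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys match the [pipelineConfig()] arguments.
#' @return list of class \code{"pipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, spec)
}

#' Run the simulate-then-analyze pipeline end to end
#'
#' For each configured archetype, generates a phantom section stack, then
#' per section: normalizes against the internal standard, computes the
#' heterogeneity report (percent positive pixels, particle statistics) at
#' the control-derived threshold, zones the section and quantifies each
#' zone in pmol/mm2 through the calibration curve, and computes the bulk
#' homogenate-equivalent amount. Across archetypes, percent-positive values
#' are compared by one-way ANOVA with Tukey's multiple comparisons.
#'
#' Writes \code{sections.csv} (one row per section), \code{zones.csv},
#' \code{groups.json} and \code{run.json} (full provenance: config, seeds,
#' threshold, calibration) into the output directory. Outputs are
#' deterministic: identical configs give byte-identical files. Zone
#' quantification of a section whose zones are too fragmented to host ROIs
#' is reported as \code{NA}.
#'
#' @param config a [pipelineConfig()] list.
#' @return (invisibly) list with \code{sections} and \code{zones} data
#'   frames, \code{groups} (the [compareGroups()] result), \code{curve},
#'   \code{threshold}, \code{outputDir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  cfg <- config
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)

  phArgs <- function(extra) {
    do.call(phantomConfig, c(list(gridShape = cfg$gridShape,
                                  nSections = cfg$nSections), extra,
                             cfg$phantomArgs[setdiff(names(cfg$phantomArgs),
                                                     names(extra))]))
  }
  probe <- phArgs(list(seed = 0))

  calib <- makeCalibrationSection(amountsPmol = cfg$calibrationAmounts,
                                  gain = probe$gain,
                                  istdNominal = probe$istdNominal,
                                  bgScale = probe$bgScale,
                                  pixelSizeUm = probe$pixelSizeUm,
                                  sRange = c(probe$sMin, probe$sMax),
                                  seed = cfg$seed * 1000 + 1)
  curve <- buildCalibration(calib$spots,
                            normalizeIntensity(calib$drug, calib$istd))

  controls <- lapply(seq_len(cfg$nControls), function(i) {
    cs <- makeControlSection(shape = cfg$gridShape, bgScale = probe$bgScale,
                             istdNominal = probe$istdNominal,
                             sMin = probe$sMin, sMax = probe$sMax,
                             correlationLengthPx = probe$correlationLengthPx,
                             pixelSizeUm = probe$pixelSizeUm,
                             seed = cfg$seed * 1000 + 100 + i)
    normalizeIntensity(cs$drug, cs$istd)
  })
  thresholdModel <- estimateThreshold(controls, k = cfg$thresholdK)

  sectionRows <- list()
  zoneRows <- list()
  for (ai in seq_along(cfg$archetypes)) {
    arch <- cfg$archetypes[ai]
    ph <- makePhantom(phArgs(list(archetype = arch,
                                  seed = cfg$seed * 1000 + 200 + ai)))
    for (si in seq_len(nSections(ph$stack))) {
      sec <- getSection(ph$stack, si)
      norm <- normalizeIntensity(sec$drug, sec$istd)
      het <- heterogeneityReport(norm, thresholdModel,
                                 connectivity = cfg$connectivity,
                                 label = sprintf("%s_s%d", arch, si))
      ps <- particleSummary(het$particles)
      bulk <- homogenateEquivalent(norm, curve)
      roiSeed <- cfg$seed * 1000 + 300 + 10 * ai + si
      zq <- tryCatch({
        zm <- zoneMap(norm, thresholdModel, fHigh = cfg$fHigh,
                      fLow = cfg$fLow)
        rois <- sampleZoneRois(zm, nPerZone = cfg$nPerZone,
                               roiPixels = cfg$roiPixels,
                               purity = cfg$purity, seed = roiSeed,
                               pixelSizeUm = probe$pixelSizeUm)
        zoneQuantify(norm, rois, curve, seed = roiSeed)
      }, error = function(e) NULL)
      sectionRows[[length(sectionRows) + 1L]] <- data.frame(
        archetype = arch, section = si,
        true_support_pct = 100 * ph$truth[[si]]@positiveSupportFraction,
        percent_positive = het$percentPositive,
        n_particles = ps$nParticles,
        mean_particle_size_mm2 = ps$meanSizeMm2,
        mean_particle_perimeter_mm = ps$meanPerimeterMm,
        mean_circularity = ps$meanCircularity,
        bulk_pmol_mm2 = bulk$amount,
        fold_high_vs_low = if (is.null(zq)) NA_real_ else zq@foldHighVsLow,
        fold_high_vs_mid = if (is.null(zq)) NA_real_ else zq@foldHighVsMid,
        roi_seed = roiSeed, stringsAsFactors = FALSE)
      if (!is.null(zq)) {
        z <- zq@zones
        z$archetype <- arch; z$section <- si
        zoneRows[[length(zoneRows) + 1L]] <- z
      }
    }
  }
  sections <- do.call(rbind, sectionRows)
  zones <- if (length(zoneRows)) do.call(rbind, zoneRows) else
    data.frame()

  groups <- NULL
  if (length(cfg$archetypes) >= 2L && cfg$nSections >= 2L) {
    groups <- compareGroups(split(sections$percent_positive,
                                  sections$archetype))
  }

  write.csv(sections, file.path(cfg$outputDir, "sections.csv"),
            row.names = FALSE)
  write.csv(zones, file.path(cfg$outputDir, "zones.csv"),
            row.names = FALSE)
  if (!is.null(groups)) {
    jsonlite::write_json(
      list(anova_f = groups$F, anova_p = groups$p,
           tukey = groups$tukey),
      file.path(cfg$outputDir, "groups.json"), auto_unbox = TRUE,
      digits = NA)
  }
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "outputDir")],
         threshold = list(value = thresholdModel@threshold,
                          mean_bg = thresholdModel@meanBg,
                          sd_bg = thresholdModel@sdBg,
                          k = thresholdModel@k,
                          n_control_pixels =
                            thresholdModel@nControlPixels),
         calibration = list(slope = curve@slope,
                            intercept = curve@intercept,
                            r_squared = curve@rSquared)),
    file.path(cfg$outputDir, "run.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(sections = sections, zones = zones, groups = groups,
                 curve = curve, threshold = thresholdModel,
                 outputDir = cfg$outputDir))
}

#' One-way ANOVA with Tukey multiple comparisons across groups
#'
#' Compares a per-group metric (percent positive pixels, particle metrics,
#' bulk amounts ...) across two or more groups with one-way ANOVA followed
#' by Tukey's HSD (Tukey-Kramer for unequal group sizes), flagging adjusted
#' p-values below 0.05.
#'
#' @param valuesByGroup named list of numeric vectors, each of length >= 2.
#' @return list with \code{F}, \code{p}, \code{df}, \code{tukey} (data
#'   frame: comparison, diff, lwr, upr, p_adj, significant) and
#'   \code{groupMeans}.
#' @examples
#' compareGroups(list(a = c(1, 2, 3), b = c(1, 2, 3)))$p  # 1
#' @export
compareGroups <- function(valuesByGroup) {
  if (length(valuesByGroup) < 2L)
    stop("need >= 2 groups")
  if (any(lengths(valuesByGroup) < 2L))
    stop("every group needs n >= 2")
  df <- data.frame(
    value = unlist(valuesByGroup, use.names = FALSE),
    group = factor(rep(names(valuesByGroup), lengths(valuesByGroup))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(F = an[1L, "F value"], p = an[1L, "Pr(>F)"],
       df = c(an[1L, "Df"], an[2L, "Df"]), tukey = tukey,
       groupMeans = vapply(valuesByGroup, mean, numeric(1L)))
}
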