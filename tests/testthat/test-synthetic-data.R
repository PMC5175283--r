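test_that("suppression fields honor bounds, constancy and determinism", {
  f <- makeSuppressionField(c(15, 15), 4, 0.7, 0.7, seed = 1)
  expect_true(all(f == 0.7))
  g <- makeSuppressionField(c(30, 30), 5, 0.4, 1.0, seed = 2)
  expect_equal(min(g), 0.4)
  expect_equal(max(g), 1.0)
  expect_identical(g, makeSuppressionField(c(30, 30), 5, 0.4, 1.0,
                                           seed = 2))
  expect_false(identical(g, makeSuppressionField(c(30, 30), 5, 0.4, 1.0,
                                                 seed = 3)))
  expect_error(makeSuppressionField(c(10, 10), 4, 0, 1), "sMin")
})

test_that("suppression fields are spatially correlated at their length scale", {
  wins <- 0L
  for (s in 1:10) {
    f <- makeSuppressionField(c(48, 48), 4, 0.4, 1, seed = 100 + s)
    lagCor <- function(L) stats::cor(as.vector(f[, 1:(48 - L)]),
                                     as.vector(f[, (L + 1):48]))
    if (lagCor(4) > lagCor(16)) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("zero-noise forward model is exactly density times gain over istd", {
  cfg <- phantomConfig(gridShape = c(25, 25), nSections = 2,
                       sprayNoiseCv = 0, detectorNoiseCv = 0, bgScale = 0,
                       seed = 91)
  ph <- makePhantom(cfg)
  for (i in 1:2) {
    s <- getSection(ph$stack, i)
    norm <- normalizeIntensity(s$drug, s$istd, istdFloor = 1e-9)
    expected <- (cfg$gain / cfg$istdNominal) *
      ph$truth[[i]]@densityMap[imageMask(norm)]
    expect_equal(intensityValues(norm)[imageMask(norm)], expected,
                 tolerance = 1e-12)
  }
})

test_that("phantom archetypes realize their compartment contracts", {
  core <- makePhantom(phantomConfig(archetype = "necrotic_core",
                                    gridShape = c(40, 40), nSections = 1,
                                    seed = 92))
  tr <- core$truth[[1]]
  inCore <- tr@compartmentMap == "necrotic"
  rim <- tr@compartmentMap == "viable"
  expect_gt(sum(inCore), 0)
  expect_lt(mean(tr@densityMap[inCore]),
            0.1 * mean(tr@densityMap[rim]))
  expect_lt(tr@positiveSupportFraction, 1)

  scant <- makePhantom(phantomConfig(archetype = "scant",
                                     supportFraction = 0.35,
                                     gridShape = c(40, 40), nSections = 1,
                                     seed = 93))
  expect_equal(scant$truth[[1]]@positiveSupportFraction, 0.35,
               tolerance = 0.05)

  patchy <- makePhantom(phantomConfig(archetype = "patchy_vascular",
                                      gridShape = c(40, 40),
                                      nSections = 1, seed = 94))
  d <- patchy$truth[[1]]@densityMap
  expect_true(any(d == 0, na.rm = TRUE))
  expect_true(any(d > 0, na.rm = TRUE))
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  cfg <- phantomConfig(gridShape = c(20, 20), nSections = 2, seed = 95)
  a <- makePhantom(cfg); b <- makePhantom(cfg)
  for (i in 1:2) {
    expect_identical(intensityValues(getSection(a$stack, i)$drug),
                     intensityValues(getSection(b$stack, i)$drug))
    expect_identical(intensityValues(getSection(a$stack, i)$istd),
                     intensityValues(getSection(b$stack, i)$istd))
    expect_identical(a$truth[[i]]@densityMap, b$truth[[i]]@densityMap)
  }
})

test_that("calibration sections expose amounts per area and overlap checks", {
  cal <- makeCalibrationSection(seed = 96)
  x <- vapply(cal$spots, function(s) s@amountPmol / areaMm2(s@roi),
              numeric(1))
  expect_equal(sort(x), c(0.2, 0.5, 1.5, 5, 10, 15) / 0.25)
  expect_equal(range(x), c(0.8, 60))
  expect_error(makeCalibrationSection(amountsPmol = c(1, 1, 2)),
               "distinct")
  expect_error(makeCalibrationSection(amountsPmol = c(-1, 1, 2)),
               "positive")
  noisefree <- makeCalibrationSection(sRange = c(1, 1), noiseCv = 0,
                                      bgScale = 0, seed = 97)
  raw <- buildCalibration(noisefree$spots, noisefree$drug)
  expect_equal(rSquared(raw), 1, tolerance = 1e-12)
  expect_equal(raw@slope, 100, tolerance = 1e-9)
})

test_that("control sections are background-only and reproducible", {
  quiet <- makeControlSection(shape = c(10, 10), bgScale = 0, seed = 98)
  expect_true(all(intensityValues(quiet$drug) == 0))
  a <- makeControlSection(shape = c(12, 12), seed = 99)
  b <- makeControlSection(shape = c(12, 12), seed = 99)
  expect_identical(intensityValues(a$drug), intensityValues(b$drug))
  expect_identical(intensityValues(a$istd), intensityValues(b$istd))
})

test_that("percent positive orders archetypes by designed support", {
  ctrl <- makeControlSection(shape = c(40, 40), sMin = 0.4, sMax = 1,
                             seed = 301)
  thr <- estimateThreshold(normalizeIntensity(ctrl$drug, ctrl$istd), k = 3)
  pp <- function(arch, s) {
    ph <- makePhantom(phantomConfig(archetype = arch,
                                    gridShape = c(40, 40), nSections = 1,
                                    seed = s))
    sec <- getSection(ph$stack, 1)
    percentPositive(normalizeIntensity(sec$drug, sec$istd), thr)
  }
  for (s in 1:5) {
    hom <- pp("homogeneous", 400 + s)
    nec <- pp("necrotic_core", 500 + s)
    sca <- pp("scant", 600 + s)
    expect_gt(hom, nec)
    expect_gt(nec, sca)
  }
})

test_that("phantom spectra round-trip through extraction", {
  ph <- makePhantom(phantomConfig(gridShape = c(12, 12), nSections = 1,
                                  seed = 104))
  s <- getSection(ph$stack, 1)
  sp <- phantomSpectra(s$drug, s$istd)
  d2 <- extractIonImage(sp, 284.2, 0.25)
  i2 <- extractIonImage(sp, 289.2, 0.25)
  m <- imageMask(s$drug)
  expect_equal(intensityValues(d2)[imageMask(d2)],
               intensityValues(s$drug)[m])
  expect_equal(intensityValues(i2)[imageMask(i2)],
               intensityValues(s$istd)[m])
})
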