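test_that("exact collinear spots give the exact line and R^2 = 1", {
  curve <- makeExactCurve(slope = 2, intercept = 1)
  expect_equal(unname(coef(curve)), c(1, 2), tolerance = 1e-12)
  expect_equal(rSquared(curve), 1, tolerance = 1e-12)
  expect_equal(amountRange(curve), c(1, 3))
  inv <- invertCalibration(curve, 5)
  expect_equal(inv$amount, 2)
  expect_false(inv$extrapolated)
})

test_that("OLS fit and R^2 match the closed-form oracle", {
  set.seed(51)
  for (rep in 1:10) {
    nspot <- sample(4:8, 1)
    x <- sort(runif(nspot, 0.5, 60))
    y <- 0.1 * x + 0.02 + rnorm(nspot, sd = 0.3)
    y <- pmax(y, 0.001)
    areaPerSpot <- 2 * 0.01
    img <- ionImage(matrix(rep(y, each = 2), nrow = 2))
    spots <- lapply(seq_len(nspot), function(j)
      calibrationSpot(pixelRoi(cbind(1:2, j)), x[j] * areaPerSpot))
    curve <- buildCalibration(spots, img)
    oracle <- olsOracle(x, y)
    expect_equal(curve@slope, oracle$slope, tolerance = 1e-10)
    expect_equal(curve@intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(rSquared(curve), oracle$r2, tolerance = 1e-10)
  }
})

test_that("calibration is invariant to ROI pixel enumeration order", {
  set.seed(52)
  img <- randomImage(c(6, 9))
  mkSpots <- function(perm) lapply(1:3, function(j) {
    co <- as.matrix(expand.grid(row = 1:6, col = (3 * j - 2):(3 * j)))
    calibrationSpot(pixelRoi(co[perm(nrow(co)), ]), j)
  })
  c1 <- buildCalibration(mkSpots(seq_len), img)
  c2 <- buildCalibration(mkSpots(function(n) rev(seq_len(n))), img)
  expect_equal(coef(c1), coef(c2))
  expect_equal(rSquared(c1), rSquared(c2))
})

test_that("degenerate calibrations are rejected", {
  img <- ionImage(matrix(1:8, 2))
  sp <- function(col, amt) calibrationSpot(pixelRoi(cbind(1:2, col)), amt)
  expect_error(buildCalibration(list(sp(1, 1), sp(2, 2)), img), ">= 3")
  expect_error(buildCalibration(list(sp(1, 1), sp(2, 1), sp(3, 1)), img),
               "distinct")
  curve <- makeExactCurve(2, 1)
  flat <- new("CalibrationCurve", slope = -1, intercept = 0, rSquared = 0.5,
              points = curve@points, amountRange = c(1, 3))
  expect_error(invertCalibration(flat, 1), "slope")
})

test_that("inversion round-trips calibration points and flags extrapolation", {
  curve <- makeExactCurve(slope = 0.5, intercept = 0.25)
  for (i in seq_len(nrow(curve@points))) {
    inv <- invertCalibration(curve, curve@points$meanSignal[i])
    expect_equal(inv$amount, curve@points$amountPerArea[i],
                 tolerance = 1e-10)
  }
  below <- invertCalibration(curve, 0.1)  # signal below the intercept
  expect_lt(below$amount, 0)
  expect_true(below$extrapolated)
  expect_true(below$belowRange)
  above <- invertCalibration(curve, 100)
  expect_true(above$aboveRange)
})

test_that("ROI quantification recovers phantom ground truth through a noise-free curve", {
  # noise-free calibration: suppression 1, no noise, no background
  cal <- makeCalibrationSection(sRange = c(1, 1), noiseCv = 0, bgScale = 0,
                                seed = 61)
  curve <- buildCalibration(cal$spots,
                            normalizeIntensity(cal$drug, cal$istd))
  expect_equal(rSquared(curve), 1, tolerance = 1e-12)
  expect_equal(curve@slope, 100 / 1000, tolerance = 1e-9)

  # noise-free phantom: constant suppression cancels, ratio = gain/istd * d
  cfg <- phantomConfig(gridShape = c(30, 30), nSections = 1,
                       sprayNoiseCv = 0, detectorNoiseCv = 0, bgScale = 0,
                       sMin = 0.6, sMax = 0.9, seed = 62)
  ph <- makePhantom(cfg)
  s1 <- getSection(ph$stack, 1)
  norm <- normalizeIntensity(s1$drug, s1$istd)
  roi <- makeCircularRoi(c(15, 15), 9, c(30, 30))
  q <- quantifyRoi(norm, roi, curve)
  truthMean <- mean(ph$truth[[1]]@densityMap[roiCoords(roi)])
  expect_equal(q$amount, truthMean, tolerance = 1e-6)
  expect_equal(q$nValidPixels, 9)

  # two disjoint ROIs with identical values quantify identically
  img <- ionImage(matrix(5, 4, 4))
  r1 <- pixelRoi(cbind(1:2, 1)); r2 <- pixelRoi(cbind(3:4, 4))
  expect_equal(quantifyRoi(img, r1, curve)$amount,
               quantifyRoi(img, r2, curve)$amount)
})

test_that("calibration JSON report and spot declarations round-trip", {
  curve <- makeExactCurve(2, 1)
  f <- tempfile(fileext = ".json")
  writeCalibrationReport(curve, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$slope, 2, tolerance = 1e-12)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)

  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(amount_pmol = 0.2,
         roi = list(kind = "circle", center = c(5, 5), n_pixels = 9)),
    list(amount_pmol = 1.5,
         roi = list(kind = "pixels", coords = list(c(1, 1), c(1, 2))))),
    f2, auto_unbox = TRUE)
  spots <- readCalibrationJson(f2, c(10, 10))
  expect_length(spots, 2)
  expect_equal(spots[[1]]@amountPmol, 0.2)
  expect_equal(nValidPixels(spots[[2]]@roi), 2)
})
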