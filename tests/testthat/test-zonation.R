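test_that("zone labels follow the section-maximum boundaries", {
  img <- ionImage(matrix(c(10, 5, 1, 0.05), 1))
  zm <- zoneMap(img, 0.1, robustMax = FALSE)
  expect_equal(as.vector(zoneLabels(zm)),
               c("high", "mid", "low", "background"))
  # value exactly at 0.75 * max is high (closed lower bound)
  img2 <- ionImage(matrix(c(10, 7.5, 2.5, 1), 1))
  lab2 <- as.vector(zoneLabels(zoneMap(img2, 0.1, robustMax = FALSE)))
  expect_equal(lab2, c("high", "high", "mid", "low"))
  expect_error(zoneMap(ionImage(matrix(c(0.01, 0.02), 1)), 0.5),
               "no signal to zone")
})

test_that("zone classification matches a per-pixel oracle and partitions", {
  set.seed(81)
  for (r in 1:50) {
    im <- randomImage(c(10, 10), 0, 10)
    thr <- runif(1, 0.1, 2)
    if (all(intensityValues(im) <= thr)) next
    zm <- zoneMap(im, thr, robustMax = FALSE)
    v <- intensityValues(im)
    mx <- max(v)
    oracle <- ifelse(v <= thr, "background",
                     ifelse(v >= 0.75 * mx, "high",
                            ifelse(v >= 0.25 * mx, "mid", "low")))
    expect_identical(zoneLabels(zm), oracle)
    counts <- table(factor(zoneLabels(zm),
                           c("high", "mid", "low", "background")))
    expect_equal(sum(counts), 100)
  }
})

test_that("masked pixels stay out of every intensity zone", {
  v <- matrix(c(10, NA, 3, 0.01), 2)
  zm <- zoneMap(ionImage(v), 0.1, robustMax = FALSE)
  expect_equal(zoneLabels(zm)[2, 1], "masked")
  expect_equal(sum(zoneLabels(zm) != "masked"), 3)
})

test_that("zone ROI sampling is feasible, pure, disjoint and reproducible", {
  lab <- matrix("background", 40, 40)
  lab[11:30, 11:30] <- "high"
  zm <- new("ZoneMap", labels = lab, fHigh = 0.75, fLow = 0.25,
            sectionMax = 1, backgroundThreshold = 0)
  rois <- sampleZoneRois(zm, nPerZone = 3, roiPixels = 25, purity = 1,
                         seed = 5, zoneNames = "high")
  expect_length(rois$high, 3)
  keys <- unlist(lapply(rois$high, function(r)
    paste(roiCoords(r)[, 1], roiCoords(r)[, 2])))
  expect_false(anyDuplicated(keys) > 0)
  for (r in rois$high)
    expect_true(all(lab[roiCoords(r)] == "high"))
  rois2 <- sampleZoneRois(zm, nPerZone = 3, roiPixels = 25, purity = 1,
                          seed = 5, zoneNames = "high")
  expect_identical(lapply(rois$high, roiCoords),
                   lapply(rois2$high, roiCoords))

  # speckled zone: accepted ROIs still honor the purity contract
  set.seed(82)
  lab2 <- matrix(ifelse(runif(1600) < 0.9, "mid", "low"), 40, 40)
  zm2 <- new("ZoneMap", labels = lab2, fHigh = 0.75, fLow = 0.25,
             sectionMax = 1, backgroundThreshold = 0)
  rois3 <- sampleZoneRois(zm2, nPerZone = 2, roiPixels = 25, purity = 0.8,
                          seed = 9, zoneNames = "mid")
  for (r in rois3$mid)
    expect_gte(mean(lab2[roiCoords(r)] == "mid"), 0.8)

  # a fragmented zone errors with its name
  lab3 <- matrix("background", 20, 20); lab3[1, 1] <- "low"
  zm3 <- new("ZoneMap", labels = lab3, fHigh = 0.75, fLow = 0.25,
             sectionMax = 1, backgroundThreshold = 0)
  expect_error(sampleZoneRois(zm3, nPerZone = 2, roiPixels = 25,
                              purity = 0.9, seed = 1, zoneNames = "low",
                              maxAttempts = 50),
               "low")
})

test_that("zone quantification reports folds and per-zone spread", {
  curve <- makeExactCurve(slope = 1, intercept = 0)
  img <- ionImage(matrix(rep(c(8, 4, 2), each = 8), nrow = 4))
  rois <- list(
    high = list(pixelRoi(as.matrix(expand.grid(1:4, 1:2)))),
    mid = list(pixelRoi(as.matrix(expand.grid(1:4, 3:4)))),
    low = list(pixelRoi(as.matrix(expand.grid(1:4, 5:6)))))
  zq <- zoneQuantify(img, rois, curve)
  expect_equal(zq@foldHighVsLow, 4)
  expect_equal(zq@foldHighVsMid, 2)
  expect_true(all(is.na(zq@zones$sdAmount)))  # single ROI per zone
  expect_equal(zq@zones$nRois, rep(1L, 3))
})

test_that("undefined folds warn when a zone mean is non-positive", {
  curve <- makeExactCurve(slope = 1, intercept = 2)  # signal 1 -> -1
  img <- ionImage(matrix(c(8, 8, 1, 1), 1))
  rois <- list(high = list(pixelRoi(rbind(c(1, 1), c(1, 2)))),
               low = list(pixelRoi(rbind(c(1, 3), c(1, 4)))))
  expect_warning(zq <- zoneQuantify(img, rois, curve), "undefined")
  expect_true(is.na(zq@foldHighVsLow))
})

test_that("bulk homogenate-equivalent hides spatial heterogeneity", {
  curve <- makeExactCurve(slope = 1, intercept = 0)
  uni <- ionImage(matrix(2, 10, 10))
  expect_equal(homogenateEquivalent(uni, curve)$amount, 2)
  sub <- quantifyRoi(uni, makeCircularRoi(c(5, 5), 9, c(10, 10)), curve)
  expect_equal(sub$amount, 2)

  clustered <- matrix(0.001, 10, 10)
  clustered[1:5, ] <- 3.999
  cl <- ionImage(clustered)
  expect_equal(homogenateEquivalent(cl, curve)$amount, 2)
  expect_equal(percentPositive(uni, 1), 100)
  expect_equal(percentPositive(cl, 1), 50)
  expect_error(homogenateEquivalent(ionImage(matrix(NA_real_, 2, 2)),
                                    curve),
               "no valid pixels")
})

test_that("zone maps export as indexed PNG", {
  img <- ionImage(matrix(c(10, 5, 1, 0.05), 2))
  zm <- zoneMap(img, 0.1, robustMax = FALSE)
  f <- tempfile(fileext = ".png")
  writeZonePng(zm, f)
  arr <- png::readPNG(f)
  expect_equal(dim(arr)[1:2], c(2L, 2L))
})
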