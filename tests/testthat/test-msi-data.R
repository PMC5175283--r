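test_that("ion-image extraction sums intensities in a closed m/z window", {
  sp <- pixelSpectra(rbind(c(1, 1)),
                     mz = list(c(283.9, 284.2, 284.5, 289.2)),
                     intensity = list(c(5, 10, 3, 7)))
  # tol 0.25 gives the closed window [283.95, 284.45]: only the 284.2 peak
  # falls inside; 283.9 and 284.5 are both excluded
  expect_equal(intensityValues(extractIonImage(sp, 284.2, 0.25))[1, 1], 10)
  # widening to 0.3 pulls in both flanking peaks (closed at 284.5)
  expect_equal(intensityValues(extractIonImage(sp, 284.2, 0.3))[1, 1], 18)
  expect_equal(intensityValues(extractIonImage(sp, 289.2, 0.25))[1, 1], 7)
  # boundary peaks are included (closed interval)
  sp2 <- pixelSpectra(rbind(c(1, 1)), mz = list(c(283.95, 284.45)),
                      intensity = list(c(2, 4)))
  expect_equal(intensityValues(extractIonImage(sp2, 284.2, 0.25))[1, 1], 6)
})

test_that("extraction spans the coordinate bounding box and masks missing pixels", {
  set.seed(41)
  coords <- rbind(c(3, 4), c(3, 5), c(4, 5))  # 2x2 box with one missing
  mzs <- lapply(1:3, function(i) sort(runif(20, 250, 300)))
  ints <- lapply(1:3, function(i) runif(20, 0, 10))
  sp <- pixelSpectra(coords, mzs, ints)
  img <- extractIonImage(sp, 284.2, 2.5)
  expect_identical(dim(intensityValues(img)), c(2L, 2L))
  expect_identical(imageMask(img), matrix(c(TRUE, FALSE, TRUE, TRUE), 2))
  # brute-force per-pixel window sums
  for (i in 1:3) {
    expected <- 0
    for (k in seq_along(mzs[[i]]))
      if (mzs[[i]][k] >= 284.2 - 2.5 && mzs[[i]][k] <= 284.2 + 2.5)
        expected <- expected + ints[[i]][k]
    expect_equal(intensityValues(img)[coords[i, 1] - 2, coords[i, 2] - 3],
                 expected)
  }
})

test_that("extraction is additive over any partition of the spectrum", {
  set.seed(7)
  for (rep in 1:10) {
    mzv <- sort(runif(30, 250, 300))
    iv <- runif(30, 0, 5)
    sp <- pixelSpectra(rbind(c(1, 1)), list(mzv), list(iv))
    whole <- intensityValues(extractIonImage(sp, 275, 25))[1, 1]
    cut <- runif(1, 251, 299)
    left <- sum(iv[mzv >= 250 & mzv <= cut])
    right <- sum(iv[mzv > cut & mzv <= 300])
    expect_equal(whole, left + right, tolerance = 1e-12)
  }
})

test_that("extraction errors name the acquired range; duplicates rejected", {
  sp <- pixelSpectra(rbind(c(1, 1)), list(c(260)), list(c(1)),
                     mzRange = c(250, 300))
  expect_error(extractIonImage(sp, 300, 0.25), "250")
  expect_error(extractIonImage(sp, 249.9, 0.05), "acquired")
  expect_error(pixelSpectra(rbind(c(1, 1), c(1, 1)),
                            list(c(260), c(261)), list(c(1), c(1))),
               "duplicate")
})

test_that("circular ROIs have exact cardinality with lexicographic ties", {
  expect_identical(roiCoords(makeCircularRoi(c(5, 5), 1, c(10, 10))),
                   matrix(c(5L, 5L), 1, dimnames = list(NULL,
                                                        c("row", "col"))))
  roi5 <- makeCircularRoi(c(5, 5), 5, c(20, 20))
  expect_identical(unname(roiCoords(roi5)),
                   rbind(c(5L, 5L), c(4L, 5L), c(5L, 4L), c(5L, 6L),
                         c(6L, 5L)))
  roi25 <- makeCircularRoi(c(10, 10), 25, c(20, 20), pixelSizeUm = 100)
  expect_equal(areaMm2(roi25), 0.25)
  expect_identical(roiCoords(roi25),
                   roiCoords(makeCircularRoi(c(10, 10), 25, c(20, 20))))
  expect_error(makeCircularRoi(c(2, 2), 10, c(3, 3)), "fewer")
  expect_error(makeCircularRoi(c(9, 2), 4, c(5, 5)), "inside")
})

test_that("ROI JSON round-trips and circle specs are realized", {
  roi <- makeCircularRoi(c(4, 4), 9, c(10, 10))
  f <- tempfile(fileext = ".json")
  writeRoiJson(roi, f)
  back <- readRoiJson(f, c(10, 10))
  expect_equal(unname(roiCoords(back)), unname(roiCoords(roi)))
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "circle", center = c(4, 4),
                            n_pixels = 9), f2, auto_unbox = TRUE)
  expect_equal(unname(roiCoords(readRoiJson(f2, c(10, 10)))),
               unname(roiCoords(roi)))
})

test_that("whole-section ROI covers exactly the valid pixels", {
  img <- ionImage(matrix(c(1, NA, 3, 4), 2))
  roi <- wholeSectionRoi(img)
  expect_equal(nValidPixels(roi), 3)
  expect_equal(rsdPercent(img, roi), 100 * sd(c(1, 3, 4)) / mean(c(1, 3, 4)))
})
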