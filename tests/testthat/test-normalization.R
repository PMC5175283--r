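test_that("normalization divides channels pixel-wise and applies the floor", {
  d <- ionImage(matrix(c(2, 4, 6, 8), 2))
  i <- ionImage(matrix(2, 2, 2))
  n <- normalizeIntensity(d, i, istdFloor = 0.1)
  expect_equal(intensityValues(n), matrix(c(1, 2, 3, 4), 2))
  expect_equal(n@nFloorMasked, 0L)

  d2 <- ionImage(matrix(c(2, 4), 1))
  i2 <- ionImage(matrix(c(2, 0.05), 1))
  n2 <- normalizeIntensity(d2, i2, istdFloor = 0.1)
  expect_equal(intensityValues(n2)[1, 1], 1)
  expect_false(imageMask(n2)[1, 2])
  expect_equal(n2@nFloorMasked, 1L)

  expect_error(normalizeIntensity(d, ionImage(matrix(1, 3, 3))), "shape")
  expect_error(normalizeIntensity(d2, ionImage(matrix(0.01, 1, 2)),
                                  istdFloor = 0.1),
               "no valid internal-standard signal")
})

test_that("a shared multiplicative suppression field cancels exactly", {
  set.seed(21)
  for (s in 1:5) {
    D <- matrix(runif(400, 0.5, 5), 20)
    I <- matrix(runif(400, 0.5, 5), 20)
    sf <- makeSuppressionField(c(20, 20), 4, 0.3, 1, seed = s)
    plain <- normalizeIntensity(ionImage(D), ionImage(I), 1e-9)
    supp <- normalizeIntensity(ionImage(sf * D), ionImage(sf * I), 1e-9)
    expect_lt(max(abs(intensityValues(plain) - intensityValues(supp))),
              1e-10)
  }
})

test_that("normalization is scale-equivariant in the drug channel", {
  set.seed(22)
  D <- matrix(runif(100, 0.5, 5), 10)
  I <- matrix(runif(100, 0.5, 5), 10)
  a <- 3.7
  n1 <- normalizeIntensity(ionImage(a * D), ionImage(I), 1e-9)
  n2 <- normalizeIntensity(ionImage(D), ionImage(I), 1e-9)
  expect_equal(intensityValues(n1), a * intensityValues(n2),
               tolerance = 1e-12)
})

test_that("RSD% matches closed forms and rejects degenerate input", {
  expect_equal(rsdPercent(ionImage(matrix(10, 1, 3))), 0)
  expect_equal(rsdPercent(ionImage(matrix(c(1, 3), 1))),
               100 * sqrt(2) / 2)
  expect_error(rsdPercent(ionImage(matrix(5, 1, 1))), ">= 2")
  expect_error(rsdPercent(ionImage(matrix(0, 2, 2))), "mean")
})

test_that("normalization reduces whole-section RSD under shared suppression", {
  ph <- makePhantom(phantomConfig(gridShape = c(50, 50), nSections = 1,
                                  seed = 31))
  s1 <- getSection(ph$stack, 1)
  rep <- rsdReport(s1$drug, s1$istd)
  expect_lt(rep$rsd_norm, rep$rsd_raw)
  expect_gt(rep$n_pixels, 100)
})

test_that("series comparison: identity, scaling, and degenerate errors", {
  ph <- makePhantom(phantomConfig(gridShape = c(24, 24), nSections = 3,
                                  seed = 41))
  cmp <- compareSeries(ph$stack, ph$stack)
  expect_equal(cmp$ratioTest$t, 0)
  expect_equal(cmp$ratioTest$p, 1)
  expect_equal(cmp$istdTest$p, 1)

  doubled <- sectionStack(lapply(ph$stack@sections, function(s) {
    list(drug = ionImage(2 * intensityValues(s$drug),
                         imageMask(s$drug)),
         istd = s$istd)
  }), group = "treated")
  cmp2 <- compareSeries(ph$stack, doubled)
  expect_equal(cmp2$ratioTest$meanB / cmp2$ratioTest$meanA, 2,
               tolerance = 1e-10)

  flat <- sectionStack(rep(list(list(drug = ionImage(matrix(1, 4, 4)),
                                     istd = ionImage(matrix(1, 4, 4)))),
                           2), group = "control")
  expect_error(compareSeries(flat, flat), "degenerate")
  one <- sectionStack(ph$stack@sections[1], group = "treated")
  expect_error(compareSeries(one, ph$stack), ">= 2 sections")
})

test_that("same-distribution section series are rarely declared different", {
  pass <- 0L
  for (r in 1:100) {
    a <- makePhantom(phantomConfig(gridShape = c(20, 20), nSections = 4,
                                   seed = 1000 + 2 * r))
    b <- makePhantom(phantomConfig(gridShape = c(20, 20), nSections = 4,
                                   seed = 1001 + 2 * r))
    cmp <- compareSeries(a$stack, b$stack)
    if (cmp$ratioTest$p > 0.05) pass <- pass + 1L
  }
  expect_gte(pass, 90L)
})
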