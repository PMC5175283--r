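# Independent oracles and fixture builders used across the suite.

# Brute-force flood-fill connected-component labeling (BFS), independent of
# the package's iterative min-label propagation. Components are numbered in
# order of their first column-major pixel, matching the package's canonical
# numbering contract.
floodFillOracle <- function(bin, connectivity) {
  nr <- nrow(bin); nc <- ncol(bin)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  lab <- matrix(0L, nr, nc)
  nid <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    nid <- nid + 1L
    queue <- start
    lab[start] <- nid
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- (cur - 1L) %% nr + 1L
      c_ <- (cur - 1L) %/% nr + 1L
      for (o in offs) {
        rr <- r + o[1L]; cc <- c_ + o[2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (!bin[rr, cc]) next
        idx <- (cc - 1L) * nr + rr
        if (lab[idx] == 0L) {
          lab[idx] <- nid
          queue <- c(queue, idx)
        }
      }
    }
  }
  list(labels = lab, n = nid)
}

# Exposed-edge perimeter of component `id` counted pixel by pixel.
perimeterOracle <- function(bin, lab, id) {
  nr <- nrow(bin); nc <- ncol(bin)
  edges <- 0L
  for (idx in which(lab == id)) {
    r <- (idx - 1L) %% nr + 1L
    c_ <- (idx - 1L) %/% nr + 1L
    for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + o[1L]; cc <- c_ + o[2L]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc || !bin[rr, cc])
        edges <- edges + 1L
    }
  }
  edges
}

# Closed-form simple-regression oracle from raw sums.
olsOracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = sxy^2 / (sxx * syy))
}

# Exact calibration curve y = slope * x + intercept built through the
# public API: three single-column spots with amounts chosen so the
# amount-per-area abscissae are 1, 2, 3 pmol/mm2.
makeExactCurve <- function(slope = 1, intercept = 0) {
  x <- c(1, 2, 3)
  areaPerSpot <- 2 * (100 / 1000)^2          # two 100-um pixels
  img <- msihet::ionImage(
    matrix(rep(slope * x + intercept, each = 2), nrow = 2))
  spots <- lapply(1:3, function(j) msihet::calibrationSpot(
    msihet::pixelRoi(cbind(1:2, j)), x[j] * areaPerSpot))
  msihet::buildCalibration(spots, img)
}

# Random positive ion image for property checks.
randomImage <- function(shape = c(12, 12), lo = 0.5, hi = 5,
                        pixelSizeUm = 100) {
  msihet::ionImage(matrix(stats::runif(prod(shape), lo, hi), shape[1L]),
                   pixelSizeUm = pixelSizeUm)
}
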