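# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
withSeed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# 1-D convolution with a symmetric kernel, "same" output length.
smooth1d <- function(v, k) {
  r <- (length(k) - 1L) / 2L
  full <- stats::convolve(v, rev(k), type = "open")
  full[(r + 1L):(r + length(v))]
}

# Separable Gaussian smoothing with edge renormalization (no wrap-around,
# constant fields stay constant).
gaussianSmooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pass <- function(m) {
    num <- vapply(seq_len(ncol(m)), function(j) smooth1d(m[, j], k),
                  numeric(nrow(m)))
    matrix(num, nrow = nrow(m))
  }
  num <- t(pass(t(pass(mat))))
  ones <- matrix(1, nrow(mat), ncol(mat))
  den <- t(pass(t(pass(ones))))
  num / den
}

# Multiplicative lognormal noise with unit mean and the given CV.
lnNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Additive Gaussian background, truncated at zero (intensities cannot be
# negative). With mean >> sd the truncation is negligible and the background
# is effectively Gaussian.
bgNoise <- function(n, mean, sd) {
  pmax(0, stats::rnorm(n, mean = mean, sd = sd))
}

# Row/col matrix shift filling exposed cells with `fill`.
shiftMat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  okr <- rs >= 1L & rs <= nr
  okc <- cs >= 1L & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc], drop = FALSE]
  out
}

# Values of `image` over `roi` (or the whole grid), valid pixels only.
roiValues <- function(image, roi = NULL) {
  v <- image@values; m <- image@mask
  if (is.null(roi)) return(v[m])
  co <- roi@coords
  if (any(co[, 1L] > nrow(v)) || any(co[, 2L] > ncol(v)))
    stop("ROI coordinates fall outside the image grid")
  idx <- cbind(co[, 1L], co[, 2L])
  keep <- m[idx]
  v[idx][keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
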