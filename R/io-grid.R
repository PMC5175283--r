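#' Read and write ion images as plain CSV grids
#'
#' The CSV grid dialect stores one numeric cell per pixel, \code{NA} for
#' masked pixels, preceded by comment headers of the form
#' \code{#pixel_size_um=100}, \code{#target_mz=284.2},
#' \code{#mz_tolerance=0.25} and \code{#label=...}. Round-trips are lossless
#' to full double precision.
#'
#' @param image an [IonImage-class].
#' @param path file path; \code{writeGrid} dispatches on the extension
#'   (\code{.csv} vs \code{.imzML}) unless \code{format} is given.
#' @param format \code{"csv"} or \code{"imzml"}.
#' @param mode imzML binary mode, \code{"continuous"} or \code{"processed"}.
#' @return \code{readGrid} returns an [IonImage-class]; \code{writeGrid}
#'   returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeGrid(ionImage(matrix(c(1, NA, 3, 4), 2)), f)
#' readGrid(f)
#' @export
writeGrid <- function(image, path, format = NULL,
                      mode = c("continuous", "processed")) {
  format <- format %||% guessGridFormat(path)
  if (format == "csv") {
    hdr <- c(
      sprintf("#pixel_size_um=%s", formatC(image@pixelSizeUm, format = "g",
                                           digits = 17)),
      sprintf("#target_mz=%s", formatC(image@targetMz, format = "g",
                                       digits = 17)),
      sprintf("#mz_tolerance=%s", formatC(image@mzTolerance, format = "g",
                                          digits = 17)),
      sprintf("#label=%s", image@label))
    rows <- apply(image@values, 1L, function(r)
      paste(ifelse(is.na(r), "NA",
                   formatC(r, format = "g", digits = 17)), collapse = ","))
    writeLines(c(hdr, rows), path)
  } else if (format == "imzml") {
    writeImzML(imageToSpectra(image), path, mode = match.arg(mode),
               meta = list(target_mz = image@targetMz,
                           mz_tolerance = image@mzTolerance,
                           label = image@label,
                           grid_rows = nrow(image@values),
                           grid_cols = ncol(image@values)))
  } else stop("unknown format: ", format)
  invisible(path)
}

#' @rdname writeGrid
#' @export
readGrid <- function(path, format = NULL) {
  format <- format %||% guessGridFormat(path)
  if (format == "csv") {
    lines <- readLines(path)
    isHdr <- startsWith(lines, "#")
    meta <- list(pixel_size_um = 100, target_mz = NA, mz_tolerance = NA,
                 label = "")
    for (h in lines[isHdr]) {
      kv <- sub("^#", "", h)
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      meta[[key]] <- val
    }
    body <- lines[!isHdr & nzchar(lines)]
    cells <- strsplit(body, ",", fixed = TRUE)
    ncols <- unique(lengths(cells))
    if (length(ncols) != 1L)
      stop("ragged CSV grid: rows have differing cell counts (",
           paste(sort(ncols), collapse = ", "), ")")
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(cells)), nrow = length(cells),
             ncol = ncols, byrow = TRUE))
    bad <- is.na(vals) & matrix(unlist(cells) != "NA", nrow = length(cells),
                                byrow = TRUE)
    if (any(bad)) stop("non-numeric cell(s) in CSV grid")
    ionImage(vals, pixelSizeUm = as.numeric(meta$pixel_size_um),
             targetMz = as.numeric(meta$target_mz),
             mzTolerance = as.numeric(meta$mz_tolerance),
             label = as.character(meta$label))
  } else if (format == "imzml") {
    readGridImzML(path)
  } else stop("unknown format: ", format)
}

guessGridFormat <- function(path) {
  if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "csv"
}

# Encode an ion image as one-peak-per-pixel spectra at its target m/z, for
# imzML serialization. Masked pixels get no spectrum.
imageToSpectra <- function(image) {
  if (is.na(image@targetMz))
    stop("image has no targetMz; set one before writing imzML")
  idx <- which(image@mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("image has no valid pixels")
  v <- image@values[idx]
  pixelSpectra(
    coords = idx,
    mz = rep(list(image@targetMz), nrow(idx)),
    intensity = lapply(v, function(x) x),
    mzRange = c(image@targetMz - 10, image@targetMz + 10),
    pixelSizeUm = image@pixelSizeUm)
}

# Rebuild an ion image from an imzML file written by writeGrid(): grid
# dimensions come from the scan settings (not the coordinate bounding box),
# so fully masked border rows survive the round trip.
readGridImzML <- function(path) {
  sp <- readImzML(path)
  meta <- attr(sp, "meta")
  mz <- as.numeric(meta$target_mz %||% NA)
  tol <- as.numeric(meta$mz_tolerance %||% 0.25)
  nr <- as.integer(meta$grid_rows %||% max(sp@coords[, 1L]))
  nc <- as.integer(meta$grid_cols %||% max(sp@coords[, 2L]))
  vals <- matrix(NA_real_, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  lo <- mz - tol; hi <- mz + tol
  for (i in seq_len(nrow(sp@coords))) {
    sel <- sp@mz[[i]] >= lo & sp@mz[[i]] <= hi
    vals[sp@coords[i, 1L], sp@coords[i, 2L]] <- sum(sp@intensity[[i]][sel])
    mask[sp@coords[i, 1L], sp@coords[i, 2L]] <- TRUE
  }
  ionImage(vals, mask, pixelSizeUm = sp@pixelSizeUm, targetMz = mz,
           mzTolerance = tol, label = as.character(meta$label %||% ""))
}
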