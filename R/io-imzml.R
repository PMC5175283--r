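# imzML 1.1 input/output.
#
# imzML stores spectral metadata in an mzML-style XML file (.imzML) and the
# numeric arrays in a sidecar binary file (.ibd) referenced by byte offset.
# In "continuous" mode all pixels share one m/z axis stored once; in
# "processed" mode every pixel carries its own m/z axis. Arrays are written
# as uncompressed 64-bit floats. The ibd starts with a 16-byte UUID that
# must match the XML header; file integrity is checked with the MD5 digest
# recorded in the XML.

IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED  <- "IMS:1000031"
IMS_UUID       <- "IMS:1000080"
IMS_MD5        <- "IMS:1000090"
IMS_POS_X      <- "IMS:1000050"
IMS_POS_Y      <- "IMS:1000051"
IMS_EXT_OFFSET <- "IMS:1000102"
IMS_EXT_LEN    <- "IMS:1000103"
IMS_EXT_ENC    <- "IMS:1000104"

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

ibdPathFor <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

rawToHex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

formatUuid <- function(hex) {
  paste(substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
        substr(hex, 17, 20), substr(hex, 21, 32), sep = "-")
}

#' Write per-pixel spectra to an imzML / ibd file pair
#'
#' @param spectra a [PixelSpectra-class]. Continuous mode requires all
#'   pixels to share an identical m/z axis.
#' @param path output path ending in \code{.imzML}; the binary companion is
#'   written next to it with extension \code{.ibd}.
#' @param mode \code{"continuous"} (shared m/z axis stored once) or
#'   \code{"processed"} (per-pixel m/z axes).
#' @param meta named list of scalar user metadata stored as
#'   \code{userParam} entries (round-tripped by [readImzML()]).
#' @return \code{path}, invisibly.
#' @seealso [readImzML()], [writeGrid()]
#' @export
writeImzML <- function(spectra, path, mode = c("continuous", "processed"),
                       meta = list()) {
  mode <- match.arg(mode)
  stopifnot(is(spectra, "PixelSpectra"))
  n <- nrow(spectra@coords)
  if (mode == "continuous") {
    mz0 <- spectra@mz[[1L]]
    same <- vapply(spectra@mz, function(m)
      length(m) == length(mz0) && all(m == mz0), logical(1L))
    if (!all(same))
      stop("continuous mode requires an identical m/z axis in every pixel")
  }

  ibd <- ibdPathFor(path)
  # Deterministic UUID: MD5 of the payload arrays.
  tmp <- tempfile()
  con <- file(tmp, "wb")
  for (i in seq_len(n)) {
    writeBin(as.double(spectra@mz[[i]]), con, size = 8, endian = "little")
    writeBin(as.double(spectra@intensity[[i]]), con, size = 8,
             endian = "little")
  }
  close(con)
  uuidHex <- unname(tools::md5sum(tmp))
  unlink(tmp)
  uuid <- as.raw(strtoi(substring(uuidHex, seq(1, 31, 2), seq(2, 32, 2)),
                        16L))

  # --- ibd ---
  con <- file(ibd, "wb")
  writeBin(uuid, con)
  pos <- 16
  mzOff <- integer(0); mzLen <- integer(0)
  intOff <- integer(0); intLen <- integer(0)
  if (mode == "continuous") {
    mz0 <- spectra@mz[[1L]]
    writeBin(as.double(mz0), con, size = 8, endian = "little")
    mzOff <- rep(pos, n); mzLen <- rep(length(mz0), n)
    pos <- pos + 8 * length(mz0)
    for (i in seq_len(n)) {
      writeBin(as.double(spectra@intensity[[i]]), con, size = 8,
               endian = "little")
      intOff[i] <- pos; intLen[i] <- length(spectra@intensity[[i]])
      pos <- pos + 8 * intLen[i]
    }
  } else {
    for (i in seq_len(n)) {
      writeBin(as.double(spectra@mz[[i]]), con, size = 8, endian = "little")
      mzOff[i] <- pos; mzLen[i] <- length(spectra@mz[[i]])
      pos <- pos + 8 * mzLen[i]
      writeBin(as.double(spectra@intensity[[i]]), con, size = 8,
               endian = "little")
      intOff[i] <- pos; intLen[i] <- length(spectra@intensity[[i]])
      pos <- pos + 8 * intLen[i]
    }
  }
  close(con)
  md5 <- toupper(unname(tools::md5sum(ibd)))

  # --- XML ---
  modeAcc <- if (mode == "continuous") IMS_CONTINUOUS else IMS_PROCESSED
  userParams <- vapply(names(meta), function(k) sprintf(
    '      <userParam name="%s" value="%s"/>', xmlEscape(k),
    xmlEscape(as.character(meta[[k]]))), character(1L))
  bda <- function(group, off, len) paste0(
    '        <binaryDataArray encodedLength="0">\n',
    sprintf('          <referenceableParamGroupRef ref="%s"/>\n', group),
    sprintf('          <cvParam cvRef="IMS" accession="%s" name="external array length" value="%d"/>\n', IMS_EXT_LEN, len),
    sprintf('          <cvParam cvRef="IMS" accession="%s" name="external encoded length" value="%d"/>\n', IMS_EXT_ENC, 8L * len),
    sprintf('          <cvParam cvRef="IMS" accession="%s" name="external offset" value="%d"/>\n', IMS_EXT_OFFSET, off),
    '          <binary/>\n',
    '        </binaryDataArray>')
  spectraXml <- vapply(seq_len(n), function(i) paste0(
    sprintf('      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
            i, i - 1L, intLen[i]),
    '        <scanList count="1">\n          <scan>\n',
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="position x" value="%d"/>\n',
            IMS_POS_X, spectra@coords[i, 2L]),
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="position y" value="%d"/>\n',
            IMS_POS_Y, spectra@coords[i, 1L]),
    '          </scan>\n        </scanList>\n',
    '        <binaryDataArrayList count="2">\n',
    bda("mzArray", mzOff[i], mzLen[i]), "\n",
    bda("intensityArray", intOff[i], intLen[i]), "\n",
    '        </binaryDataArrayList>\n',
    '      </spectrum>'), character(1L))

  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <cvList count="3">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n    <fileContent>\n',
    sprintf('      <cvParam cvRef="IMS" accession="%s" name="%s"/>\n',
            modeAcc, mode),
    sprintf('      <cvParam cvRef="IMS" accession="%s" name="universally unique identifier" value="{%s}"/>\n',
            IMS_UUID, formatUuid(uuidHex)),
    sprintf('      <cvParam cvRef="IMS" accession="%s" name="ibd MD5" value="%s"/>\n',
            IMS_MD5, md5),
    '      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>\n',
    '    </fileContent>\n  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <softwareList count="1">\n',
    '    <software id="msihet" version="0.99.0"/>\n',
    '  </softwareList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scanSettings1">\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
            max(spectra@coords[, 2L])),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
            max(spectra@coords[, 1L])),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>\n',
            spectra@pixelSizeUm),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>\n',
            spectra@pixelSizeUm),
    sprintf('      <userParam name="mz_range_lo" value="%.17g"/>\n',
            spectra@mzRange[1L]),
    sprintf('      <userParam name="mz_range_hi" value="%.17g"/>\n',
            spectra@mzRange[2L]),
    if (length(userParams)) paste0(paste(userParams, collapse = "\n"), "\n")
    else "",
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="export">\n',
    '      <processingMethod order="1" softwareRef="msihet">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
    '      </processingMethod>\n',
    '    </dataProcessing>\n',
    '  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="export">\n', n),
    paste(spectraXml, collapse = "\n"), "\n",
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

cvValue <- function(doc, accession) {
  node <- xml2::xml_find_first(doc, sprintf(
    "//*[local-name()='cvParam'][@accession='%s']", accession))
  if (inherits(node, "xml_missing")) return(NULL)
  xml2::xml_attr(node, "value")
}

#' Read an imzML / ibd file pair
#'
#' Parses the XML header, validates the ibd companion (UUID match, MD5
#' digest when present, offset/length bounds) and reads all spectra.
#' Both continuous and processed binary modes are supported.
#'
#' @param path path to the \code{.imzML} file; the \code{.ibd} companion
#'   must sit next to it.
#' @return A [PixelSpectra-class] with attribute \code{meta} holding any
#'   \code{userParam} metadata.
#' @seealso [writeImzML()], [readGrid()]
#' @export
readImzML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed imzML XML in '", path,
                                           "': ", conditionMessage(e)))
  ibd <- ibdPathFor(path)
  if (!file.exists(ibd)) stop("missing ibd companion file: ", ibd)

  modeCont <- !inherits(xml2::xml_find_first(doc, sprintf(
    "//*[local-name()='cvParam'][@accession='%s']", IMS_CONTINUOUS)),
    "xml_missing")

  uuidXml <- cvValue(doc, IMS_UUID)
  md5Xml <- cvValue(doc, IMS_MD5)
  ibdSize <- file.size(ibd)
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  uuidIbd <- rawToHex(readBin(con, "raw", n = 16L))
  if (!is.null(uuidXml)) {
    norm <- tolower(gsub("[^0-9a-fA-F]", "", uuidXml))
    if (!identical(norm, uuidIbd))
      stop("ibd UUID does not match the imzML header")
  }
  if (!is.null(md5Xml)) {
    if (!identical(toupper(unname(tools::md5sum(ibd))), toupper(md5Xml)))
      stop("ibd MD5 checksum mismatch: binary file is corrupt or truncated")
  }

  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  n <- length(spectra)
  if (n == 0L) stop("imzML file contains no spectra")
  coords <- matrix(0L, n, 2L)
  mzL <- vector("list", n); intL <- vector("list", n)
  spParam <- function(node, accession) {
    p <- xml2::xml_find_first(node, sprintf(
      ".//*[local-name()='cvParam'][@accession='%s']", accession))
    as.numeric(xml2::xml_attr(p, "value"))
  }
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    coords[i, ] <- c(spParam(sp, IMS_POS_Y), spParam(sp, IMS_POS_X))
    arrays <- xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']")
    for (arr in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(
        arr, ".//*[local-name()='referenceableParamGroupRef']"), "ref")
      off <- spParam(arr, IMS_EXT_OFFSET)
      len <- spParam(arr, IMS_EXT_LEN)
      if (!is.finite(off) || !is.finite(len))
        stop("binaryDataArray without external offset/length")
      if (off + 8 * len > ibdSize)
        stop(sprintf(
          "ibd length mismatch: array at offset %.0f (+%.0f bytes) exceeds file size %.0f",
          off, 8 * len, ibdSize))
      seek(con, where = off, origin = "start")
      vals <- readBin(con, "double", n = len, size = 8, endian = "little")
      if (identical(ref, "mzArray")) mzL[[i]] <- vals else intL[[i]] <- vals
    }
    if (is.null(mzL[[i]]) || is.null(intL[[i]]))
      stop("spectrum ", i, " lacks an m/z or intensity array")
  }

  ups <- xml2::xml_find_all(doc, "//*[local-name()='userParam']")
  meta <- stats::setNames(
    as.list(xml2::xml_attr(ups, "value")), xml2::xml_attr(ups, "name"))
  pxNode <- cvValue(doc, "IMS:1000046")
  px <- if (is.null(pxNode)) 100 else as.numeric(pxNode)
  lo <- as.numeric(meta$mz_range_lo %||% NA)
  hi <- as.numeric(meta$mz_range_hi %||% NA)
  allMz <- unlist(mzL)
  if (!is.finite(lo)) lo <- min(allMz) - 1
  if (!is.finite(hi)) hi <- max(allMz) + 1
  out <- pixelSpectra(coords, mzL, intL, mzRange = c(lo, hi),
                      pixelSizeUm = px)
  attr(out, "meta") <- meta[setdiff(names(meta),
                                    c("mz_range_lo", "mz_range_hi"))]
  out
}
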