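# Serial-section MSI input/output: centroid imzML 1.1 read/write on a common
# feature axis, NRRD volume export/import, and the sample-sheet manifest.
#
# imzML is the open MSI interchange format: an XML index (*.imzML) plus an
# external binary file (*.ibd) holding the m/z and intensity arrays. Only
# "processed" (centroid, per-pixel peak list) mode is supported; profile-mode
# files are out of scope.

IMZML_NS <- "http://psi.hupo.org/ms/mzml"

# deterministic 16-byte pseudo-UUID from the payload bytes (FNV-1a expanded
# by an xorshift stream) so identical content writes identical files
.contentUuid <- function(raw) {
  h1 <- 5381; h2 <- 52711
  step <- max(1L, length(raw) %/% 4096L)
  for (i in seq(1L, length(raw), by = step)) {
    b <- as.integer(raw[i])
    h1 <- (h1 * 33 + b) %% 2147483629
    h2 <- (h2 * 39 + b + 1) %% 2147483587
  }
  out <- integer(16)
  x <- h1
  for (i in 1:16) {
    x <- (x * 1103515245 + 12345 + h2) %% 2147483629
    out[i] <- x %% 256
  }
  as.raw(out)
}

.uuidString <- function(bytes) {
  hx <- paste(sprintf("%02x", as.integer(bytes)), collapse = "")
  paste(substr(hx, 1, 8), substr(hx, 9, 12), substr(hx, 13, 16),
        substr(hx, 17, 20), substr(hx, 21, 32), sep = "-")
}

.ibdPath <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

#' Write one section as a centroid imzML file
#'
#' Writes one spectrum per foreground pixel (peaks only where the intensity
#' is nonzero, at the axis m/z values), in imzML "processed" mode with
#' 64-bit m/z and intensity arrays in the companion .ibd file. The full grid
#' size is recorded in the scan settings so a round trip through
#' \code{\link{readSectionImzML}} reproduces the section bit-exactly.
#'
#' @param section a \linkS4class{SectionImage}.
#' @param axis the \linkS4class{FeatureAxis} giving peak m/z positions.
#' @param path output path ending in .imzML; the .ibd is written next to it.
#' @return invisibly, the imzML path.
#' @export
writeSectionImzML <- function(section, axis, path) {
  stopifnot(is(section, "SectionImage"), is(axis, "FeatureAxis"))
  d <- dim(section@intensities)
  if (d[3] != length(axis@mz))
    stop("section channel count does not match the feature axis")
  fg <- which(section@mask, arr.ind = TRUE)   # (row, col), 1-based
  if (nrow(fg) == 0L)
    stop("section has no foreground pixels; nothing to write")
  ord <- order(fg[, 1], fg[, 2])
  fg <- fg[ord, , drop = FALSE]

  # assemble the binary payload: per spectrum, m/z then intensity doubles
  specs <- vector("list", nrow(fg))
  for (k in seq_len(nrow(fg))) {
    v <- section@intensities[fg[k, 1], fg[k, 2], ]
    nz <- which(v > 0)
    specs[[k]] <- list(x = fg[k, 2], y = fg[k, 1],
                       mz = axis@mz[nz], int = v[nz])
  }
  payload <- lapply(specs, function(s)
    c(writeBin(s$mz, raw(), size = 8, endian = "little"),
      writeBin(s$int, raw(), size = 8, endian = "little")))
  body <- do.call(c, payload)
  uuid <- .contentUuid(body)

  ibd <- .ibdPath(path)
  con <- file(ibd, "wb")
  writeBin(uuid, con)
  writeBin(body, con)
  close(con)
  md5 <- unname(tools::md5sum(ibd))

  offset <- 16
  rows <- character(length(specs))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    n <- length(s$mz)
    mzOff <- offset; intOff <- offset + 8 * n
    offset <- offset + 16 * n
    rows[k] <- sprintf(
'   <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">
    <referenceableParamGroupRef ref="spectrum1"/>
    <scanList count="1">
     <scan>
      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
     </scan>
    </scanList>
    <binaryDataArrayList count="2">
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="mzArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
      <binary/>
     </binaryDataArray>
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="intensityArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
      <binary/>
     </binaryDataArray>
    </binaryDataArrayList>
   </spectrum>', k, k - 1L, n, s$x, s$y, n, 8 * n, mzOff, n, 8 * n, intOff)
  }

  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="%s" version="1.1">
 <cvList count="3">
  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
  <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
  <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>
 </cvList>
 <fileDescription>
  <fileContent>
   <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
   <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>
  </fileContent>
 </fileDescription>
 <referenceableParamGroupList count="3">
  <referenceableParamGroup id="spectrum1">
   <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
  </referenceableParamGroup>
  <referenceableParamGroup id="mzArray">
   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
  </referenceableParamGroup>
  <referenceableParamGroup id="intensityArray">
   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>
   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
  </referenceableParamGroup>
 </referenceableParamGroupList>
 <softwareList count="1">
  <software id="vox3dmsi" version="%s"/>
 </softwareList>
 <scanSettingsList count="1">
  <scanSettings id="scanSettings1">
   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
   <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>
   <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>
  </scanSettings>
 </scanSettingsList>
 <instrumentConfigurationList count="1">
  <instrumentConfiguration id="IC1"/>
 </instrumentConfigurationList>
 <dataProcessingList count="1">
  <dataProcessing id="export">
   <processingMethod order="1" softwareRef="vox3dmsi">
    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
   </processingMethod>
  </dataProcessing>
 </dataProcessingList>
 <run id="run1" defaultInstrumentConfigurationRef="IC1">
  <spectrumList count="%d" defaultDataProcessingRef="export">
%s
  </spectrumList>
 </run>
</mzML>
', IMZML_NS, .uuidString(uuid), md5, as.character(utils::packageVersion("vox3dmsi")),
   d[2], d[1], section@pixelSizeUm, section@pixelSizeUm,
   length(specs), paste(rows, collapse = "\n"))

  ok <- tryCatch({ writeLines(xml, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write imzML file: ", path)
  invisible(path)
}

.cvValue <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

#' Read one centroid imzML file onto a feature axis
#'
#' Every centroid peak is assigned to the nearest axis entry within the axis
#' ppm tolerance; intensities of peaks colliding on one entry are summed
#' (conserving ion counts). Pixels present in the file are foreground;
#' pixels absent are background with zero intensity. imzML 1-based pixel
#' coordinates are shifted so the grid origin is row/column 1; the grid size
#' is taken from the scan settings when recorded, otherwise from the
#' bounding box of the listed pixels.
#'
#' @param path path to the .imzML file (the .ibd must sit next to it).
#' @param axis a \linkS4class{FeatureAxis}.
#' @param zIndex z position of this section in the stack (0-based).
#' @param pixelSizeUm fallback raster size when absent from the file.
#' @param thicknessUm section thickness in um (not stored in imzML).
#' @return a \linkS4class{SectionImage}.
#' @export
readSectionImzML <- function(path, axis, zIndex = 0L, pixelSizeUm = 20,
                             thicknessUm = 20) {
  stopifnot(is(axis, "FeatureAxis"))
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("imzML parse error in '", path, "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  mode <- xml2::xml_find_first(doc, ".//fileContent/cvParam[@accession='IMS:1000031']")
  if (inherits(mode, "xml_missing") &&
      !inherits(xml2::xml_find_first(
        doc, ".//fileContent/cvParam[@accession='IMS:1000030']"), "xml_missing"))
    stop("imzML parse error in '", path,
         "': continuous (profile-grid) mode is not supported; expected processed/centroid mode")

  ss <- xml2::xml_find_first(doc, ".//scanSettings")
  gridW <- gridH <- NA_integer_
  if (!inherits(ss, "xml_missing")) {
    gridW <- suppressWarnings(as.integer(.cvValue(ss, "IMS:1000042")))
    gridH <- suppressWarnings(as.integer(.cvValue(ss, "IMS:1000043")))
    px <- suppressWarnings(as.numeric(.cvValue(ss, "IMS:1000046")))
    if (is.finite(px) && px > 0) pixelSizeUm <- px
  }

  specNodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(specNodes) == 0L)
    stop("imzML parse error in '", path, "': no spectrum records found")

  ibd <- .ibdPath(path)
  if (!file.exists(ibd))
    stop("imzML parse error in '", path, "': companion ibd file '", ibd,
         "' not found")
  ibdRaw <- readBin(ibd, "raw", n = file.size(ibd))

  nSpec <- length(specNodes)
  px <- integer(nSpec); py <- integer(nSpec)
  peaks <- vector("list", nSpec)
  for (k in seq_len(nSpec)) {
    sp <- specNodes[[k]]
    specId <- xml2::xml_attr(sp, "id")
    x <- suppressWarnings(as.integer(.cvValue(sp, "IMS:1000050")))
    y <- suppressWarnings(as.integer(.cvValue(sp, "IMS:1000051")))
    if (is.na(x) || is.na(y))
      stop("imzML parse error in '", path, "': spectrum record '", specId,
           "' lacks pixel position cvParams")
    px[k] <- x; py[k] <- y
    arrs <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- int <- numeric(0)
    for (a in arrs) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      n <- suppressWarnings(as.integer(.cvValue(a, "IMS:1000103")))
      off <- suppressWarnings(as.numeric(.cvValue(a, "IMS:1000102")))
      enc <- suppressWarnings(as.numeric(.cvValue(a, "IMS:1000104")))
      if (is.na(n) || is.na(off))
        stop("imzML parse error in '", path, "': spectrum record '", specId,
             "' has a binary array without external offset/length")
      size <- if (!is.na(enc) && n > 0) enc / n else 8
      if (!size %in% c(4, 8))
        stop("imzML parse error in '", path, "': spectrum record '", specId,
             "' uses an unsupported binary word size")
      if (off + n * size > length(ibdRaw))
        stop("imzML parse error in '", path, "': spectrum record '", specId,
             "' points beyond the end of the ibd file")
      vals <- if (n > 0)
        readBin(ibdRaw[(off + 1):(off + n * size)], "double", n = n,
                size = size, endian = "little") else numeric(0)
      if (identical(ref, "mzArray")) mz <- vals
      else if (identical(ref, "intensityArray")) int <- vals
    }
    if (length(mz) != length(int))
      stop("imzML parse error in '", path, "': spectrum record '", specId,
           "' has mismatched m/z and intensity array lengths")
    peaks[[k]] <- list(mz = mz, int = int)
  }

  if (is.na(gridW) || is.na(gridH)) {
    x0 <- min(px); y0 <- min(py)
    px <- px - x0 + 1L; py <- py - y0 + 1L
    gridW <- max(px); gridH <- max(py)
  } else if (max(px) > gridW || max(py) > gridH || min(px) < 1L || min(py) < 1L) {
    stop("imzML parse error in '", path,
         "': pixel positions fall outside the declared grid")
  }

  nF <- length(axis@mz)
  inten <- array(0, dim = c(gridH, gridW, nF))
  mask <- matrix(FALSE, gridH, gridW)
  anyMatch <- FALSE
  for (k in seq_len(nSpec)) {
    mask[py[k], px[k]] <- TRUE
    pk <- peaks[[k]]
    if (length(pk$mz) == 0L) next
    idx <- matchFeatures(axis, pk$mz)
    keep <- !is.na(idx)
    if (!any(keep)) next
    anyMatch <- TRUE
    acc <- rowsum(pk$int[keep], idx[keep])
    inten[py[k], px[k], as.integer(rownames(acc))] <- acc[, 1]
  }
  hadPeaks <- any(vapply(peaks, function(p) length(p$mz) > 0, logical(1)))
  if (hadPeaks && !anyMatch)
    stop("empty section: no peak in '", path,
         "' matches any feature-axis entry within ", axis@tolerancePpm, " ppm")

  SectionImage(inten, mask, pixelSizeUm = pixelSizeUm,
               thicknessUm = thicknessUm, zIndex = zIndex)
}

#' Match query m/z values to feature-axis entries
#'
#' Nearest-entry matching within the axis ppm tolerance.
#'
#' @param axis a \linkS4class{FeatureAxis}.
#' @param mz numeric query m/z values.
#' @return integer axis indices, NA where no entry lies within tolerance.
#' @export
matchFeatures <- function(axis, mz) {
  ref <- axis@mz
  lo <- findInterval(mz, ref)
  hi <- pmin(lo + 1L, length(ref))
  lo <- pmax(lo, 1L)
  dlo <- abs(mz - ref[lo]); dhi <- abs(mz - ref[hi])
  idx <- ifelse(dhi < dlo, hi, lo)
  ppm <- abs(mz - ref[idx]) / ref[idx] * 1e6
  ifelse(ppm <= axis@tolerancePpm, idx, NA_integer_)
}

# ---------------------------------------------------------------------------
# NRRD
# ---------------------------------------------------------------------------

#' Write a voxel volume as NRRD
#'
#' Single-file NRRD (raw encoding, little-endian) with axis order (z, y, x)
#' fastest-to-slowest, voxel spacings (thickness, pixel, pixel) in
#' micrometres, and a trailing feature axis for multichannel volumes.
#' Integer label volumes are written losslessly as int32.
#'
#' @param x a \linkS4class{FeatureVolume}, \linkS4class{LabeledObjects}, or
#'   a 3D/4D numeric or integer array.
#' @param path output file path (.nrrd).
#' @param voxelUm voxel edge lengths (dz, dy, dx) in um; required for bare
#'   arrays, taken from the object otherwise.
#' @return invisibly, the path.
#' @export
writeVolumeNrrd <- function(x, path, voxelUm = NULL) {
  if (is(x, "FeatureVolume")) { voxelUm <- x@voxelUm; x <- x@data }
  else if (is(x, "LabeledObjects")) { voxelUm <- x@voxelUm; x <- x@labels }
  if (!is.array(x) || !length(x) || !length(dim(x)) %in% 3:4)
    stop("volume must be a non-empty 3D or 4D array")
  if (is.null(voxelUm) || length(voxelUm) != 3L)
    stop("voxelUm (dz, dy, dx) is required")
  d <- dim(x)
  isInt <- is.integer(x)
  spac <- c(voxelUm, if (length(d) == 4L) NA)
  hdr <- c("NRRD0004",
           "# axis order: z y x (fastest to slowest)" ,
           paste0("type: ", if (isInt) "int32" else "double"),
           paste0("dimension: ", length(d)),
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("spacings: ", paste(ifelse(is.na(spac), "nan", spac),
                                      collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write NRRD file: ", path))
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.vector(x), con, size = if (isInt) 4 else 8, endian = "little")
  invisible(path)
}

#' Read an NRRD volume written by \code{\link{writeVolumeNrrd}}
#'
#' Supports raw-encoded little-endian single-file NRRD with int32 or double
#' payload.
#'
#' @param path NRRD file path.
#' @return list with \code{data} (array) and \code{voxelUm} (numeric(3)).
#' @export
readVolumeNrrd <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10))
  blank <- nl[which(diff(nl) == 1L)[1] + 1L]   # end of the empty line
  if (is.na(blank)) stop("malformed NRRD header (no blank line): ", path)
  hdr <- strsplit(rawToChar(raw[1:(blank - 1L)]), "\n", fixed = TRUE)[[1]]
  if (!startsWith(hdr[1], "NRRD"))
    stop("not an NRRD file: ", path)
  fields <- list()
  for (ln in hdr[-1]) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    fields[[kv[1]]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  type <- fields$type
  if (!identical(fields$encoding, "raw"))
    stop("only raw-encoded NRRD is supported")
  n <- prod(sizes)
  payload <- raw[(blank + 1L):length(raw)]
  data <- switch(type,
    int32 = , int = readBin(payload, "integer", n = n, size = 4,
                            endian = "little"),
    double = readBin(payload, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NRRD type: ", type))
  spac <- suppressWarnings(
    as.numeric(strsplit(fields$spacings, " ")[[1]]))
  list(data = array(data, dim = sizes), voxelUm = spac[1:3])
}

# ---------------------------------------------------------------------------
# Manifest and dataset assembly
# ---------------------------------------------------------------------------

#' Read a serial-section dataset from a sample-sheet manifest
#'
#' The manifest is tab-delimited with columns \code{sample_id},
#' \code{z_index} and \code{path}. z order is taken from the manifest, never
#' from filenames; relative paths resolve against the manifest directory.
#'
#' @param manifestPath path to the manifest TSV.
#' @param axis a \linkS4class{FeatureAxis}.
#' @param sampleId which sample to load (default: the only one present).
#' @param pixelSizeUm,thicknessUm geometry passed to the section reader.
#' @return a \linkS4class{SerialSectionDataset}.
#' @export
readDataset <- function(manifestPath, axis, sampleId = NULL,
                        pixelSizeUm = 20, thicknessUm = 20) {
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "z_index", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns sample_id, z_index, path")
  if (is.null(sampleId)) {
    ids <- unique(man$sample_id)
    if (length(ids) != 1L)
      stop("manifest holds several samples (", paste(ids, collapse = ", "),
           "); pick one with sampleId=")
    sampleId <- ids
  }
  man <- man[man$sample_id == sampleId, , drop = FALSE]
  if (!nrow(man)) stop("sample '", sampleId, "' not found in manifest")
  man <- man[order(man$z_index), , drop = FALSE]
  if (!identical(as.integer(man$z_index), seq_len(nrow(man)) - 1L))
    stop("z_index values must be consecutive from 0 for sample '",
         sampleId, "'")
  base <- dirname(manifestPath)
  secs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    readSectionImzML(p, axis, zIndex = as.integer(man$z_index[i]),
                     pixelSizeUm = pixelSizeUm, thicknessUm = thicknessUm)
  })
  SerialSectionDataset(secs, axis, sampleId = sampleId)
}

#' Write a dataset as per-section imzML files plus a manifest
#'
#' @param dataset a \linkS4class{SerialSectionDataset}.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  secs <- dataset@sections
  paths <- sprintf("section_%03d.imzML", vapply(secs, zIndex, integer(1)))
  for (i in seq_along(secs))
    writeSectionImzML(secs[[i]], dataset@featureAxis, file.path(dir, paths[i]))
  man <- data.frame(sample_id = dataset@sampleId,
                    z_index = vapply(secs, zIndex, integer(1)),
                    path = paths)
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
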