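# Minimal imzML reader/writer. imzML stores one XML index file (*.imzML)
# plus a binary array file (*.ibd) whose first 16 bytes are a UUID echoed
# in the XML; array locations are given as external offset / length
# cvParams. Both storage dialects are supported: "continuous" (one shared
# m/z axis, one intensity block per pixel) and "processed" (per-pixel m/z
# and intensity arrays, possibly ragged). The ibd MD5 checksum is written
# and verified on read.

.ibd_path <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

.new_uuid <- function() {
  bytes <- as.integer(c(floor(stats::runif(16, 0, 256))))
  bytes[7] <- bitwOr(bitwAnd(bytes[7], 15L), 64L)   # version 4
  bytes[9] <- bitwOr(bitwAnd(bytes[9], 63L), 128L)  # variant
  bytes
}

.uuid_string <- function(bytes) {
  h <- sprintf("%02x", bytes)
  paste0(paste0(h[1:4], collapse = ""), "-", paste0(h[5:6], collapse = ""),
         "-", paste0(h[7:8], collapse = ""), "-",
         paste0(h[9:10], collapse = ""), "-", paste0(h[11:16], collapse = ""))
}

.cv <- function(cvRef, accession, name, value = NULL, unit = NULL) {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  u <- if (is.null(unit)) "" else
    sprintf(' unitCvRef="UO" unitAccession="%s" unitName="%s"',
            unit[1], unit[2])
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>',
          cvRef, accession, name, v, u)
}

#' Write a cube as imzML
#'
#' @param cube a `spectra_cube` (matrix form).
#' @param path output `.imzML` path; the `.ibd` goes alongside.
#' @param mode `"continuous"` (shared m/z axis stored once) or
#'   `"processed"` (per-pixel arrays; zero-intensity points are dropped,
#'   yielding ragged centroid-like spectra).
#' @return `path`, invisibly.
#' @export
write_imzml <- function(cube, path, mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cube, "spectra_cube"), !is.null(cube$intensity))
  ibd <- .ibd_path(path)
  uuid <- .new_uuid()
  con <- file(ibd, "wb")
  writeBin(as.raw(uuid), con)
  offset <- 16
  n_px <- nrow(cube$intensity)
  entries <- vector("list", n_px)
  put <- function(x) {
    writeBin(as.double(x), con, size = 8, endian = "little")
    start <- offset
    offset <<- offset + 8 * length(x)
    c(offset = start, length = length(x), encoded = 8 * length(x))
  }
  if (mode == "continuous") {
    mz_entry <- put(cube$mz)
    for (p in seq_len(n_px)) {
      entries[[p]] <- list(mz = mz_entry, int = put(cube$intensity[p, ]))
    }
  } else {
    for (p in seq_len(n_px)) {
      keep <- cube$intensity[p, ] > 0
      if (!any(keep)) keep[1] <- TRUE   # keep one point for empty pixels
      entries[[p]] <- list(mz = put(cube$mz[keep]),
                           int = put(cube$intensity[p, keep]))
    }
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd))

  mode_cv <- if (mode == "continuous") {
    .cv("IMS", "IMS:1000030", "continuous")
  } else {
    .cv("IMS", "IMS:1000031", "processed")
  }
  spectra <- vapply(seq_len(n_px), function(p) {
    e <- entries[[p]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              p - 1L, p, e$int[["length"]]),
      '<scanList count="1"><scan>',
      .cv("IMS", "IMS:1000050", "position x", cube$coords$col[p] + 1L),
      .cv("IMS", "IMS:1000051", "position y", cube$coords$row[p] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      .cv("IMS", "IMS:1000102", "external offset", e$mz[["offset"]]),
      .cv("IMS", "IMS:1000103", "external array length", e$mz[["length"]]),
      .cv("IMS", "IMS:1000104", "external encoded length", e$mz[["encoded"]]),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      .cv("IMS", "IMS:1000102", "external offset", e$int[["offset"]]),
      .cv("IMS", "IMS:1000103", "external array length", e$int[["length"]]),
      .cv("IMS", "IMS:1000104", "external encoded length", e$int[["encoded"]]),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, "")

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    mode_cv,
    .cv("IMS", "IMS:1000080", "universally unique identifier",
        paste0("{", .uuid_string(uuid), "}")),
    .cv("IMS", "IMS:1000090", "ibd MD5", toupper(md5)),
    .cv("MS", "MS:1000129", "negative scan"),
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    .cv("MS", "MS:1000514", "m/z array", unit = c("MS:1000040", "m/z")),
    .cv("MS", "MS:1000523", "64-bit float"),
    .cv("MS", "MS:1000576", "no compression"),
    .cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    .cv("MS", "MS:1000515", "intensity array",
        unit = c("MS:1000131", "number of detector counts")),
    .cv("MS", "MS:1000523", "64-bit float"),
    .cv("MS", "MS:1000576", "no compression"),
    .cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>\n',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    .cv("IMS", "IMS:1000042", "max count of pixels x", cube$width_px),
    .cv("IMS", "IMS:1000043", "max count of pixels y", cube$height_px),
    .cv("IMS", "IMS:1000046", "pixel size x", cube$pixel_size_um,
        unit = c("UO:0000017", "micrometer")),
    .cv("IMS", "IMS:1000047", "pixel size y", cube$pixel_size_um,
        unit = c("UO:0000017", "micrometer")),
    '</scanSettings></scanSettingsList>\n',
    '<softwareList count="1"><software id="lipidseg" version="0.1">',
    .cv("MS", "MS:1000799", "custom unreleased software tool", "lipidseg"),
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="lipidseg">',
    .cv("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n<spectrumList count="',
    n_px, '" defaultDataProcessingRef="export">\n',
    paste0(spectra, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(xml, path)
  invisible(path)
}

.xml_cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NULL)
  xml2::xml_attr(p, "value")
}

#' Read an imzML file
#'
#' Accepts both the continuous and processed dialects; the ibd MD5
#' checksum (when present) is verified before any array is read. A
#' missing polarity is assumed negative with a warning.
#'
#' @param path `.imzML` path (`.ibd` expected alongside).
#' @return a `spectra_cube`. Continuous files come back in matrix form;
#'   processed files carry a `spectra` list (per-pixel `mz`/`intensity`,
#'   possibly ragged) with `intensity = NULL` — see [cube_to_grid()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd <- .ibd_path(path)
  if (!file.exists(ibd)) stop("missing ibd file: ", ibd)
  doc <- xml2::read_xml(path)

  md5_stored <- .xml_cv_value(doc, "IMS:1000090")
  if (!is.null(md5_stored)) {
    md5 <- toupper(unname(tools::md5sum(ibd)))
    if (!identical(md5, toupper(md5_stored))) {
      stop("ibd integrity error: MD5 mismatch (stored ", md5_stored,
           ", computed ", md5, ")")
    }
  }
  continuous <- !is.null(xml2::xml_find_first(
    doc, ".//d1:cvParam[@accession='IMS:1000030']")) &&
    !inherits(xml2::xml_find_first(
      doc, ".//d1:cvParam[@accession='IMS:1000030']"), "xml_missing")
  neg <- xml2::xml_find_first(doc, ".//d1:cvParam[@accession='MS:1000129']")
  pos <- xml2::xml_find_first(doc, ".//d1:cvParam[@accession='MS:1000130']")
  polarity <- if (!inherits(neg, "xml_missing")) "negative"
  else if (!inherits(pos, "xml_missing")) "positive"
  else {
    warning("no polarity recorded; assuming negative-ion mode")
    "negative"
  }
  px <- as.numeric(.xml_cv_value(doc, "IMS:1000046") %||% NA)
  wx <- as.integer(.xml_cv_value(doc, "IMS:1000042") %||% NA)
  hy <- as.integer(.xml_cv_value(doc, "IMS:1000043") %||% NA)

  spectra_nodes <- xml2::xml_find_all(doc, ".//d1:spectrum")
  n_px <- length(spectra_nodes)
  if (n_px == 0) stop("no spectra in ", path)
  ibd_size <- file.info(ibd)$size
  con <- file(ibd, "rb")
  on.exit(close(con))
  read_entry <- function(node, which) {
    arr <- xml2::xml_find_all(node, ".//d1:binaryDataArray")
    ref <- vapply(arr, function(a)
      xml2::xml_attr(xml2::xml_find_first(a, ".//d1:referenceableParamGroupRef"),
                     "ref"), "")
    a <- arr[[match(which, ref)]]
    off <- as.numeric(.xml_cv_value(a, "IMS:1000102"))
    len <- as.integer(.xml_cv_value(a, "IMS:1000103"))
    if (off + 8 * len > ibd_size) {
      stop("ibd integrity error: array extends past end of file (truncated ibd?)")
    }
    seek(con, off)
    readBin(con, "double", n = len, size = 8, endian = "little")
  }
  coords <- data.frame(row = integer(n_px), col = integer(n_px))
  spectra <- vector("list", n_px)
  for (p in seq_len(n_px)) {
    node <- spectra_nodes[[p]]
    coords$col[p] <- as.integer(.xml_cv_value(node, "IMS:1000050")) - 1L
    coords$row[p] <- as.integer(.xml_cv_value(node, "IMS:1000051")) - 1L
    spectra[[p]] <- list(mz = read_entry(node, "mzArray"),
                         intensity = read_entry(node, "intensityArray"))
  }

  base <- list(coords = coords,
               width_px = wx %||% (max(coords$col) + 1L),
               height_px = hy %||% (max(coords$row) + 1L),
               pixel_size_um = px, polarity = polarity)
  if (continuous) {
    mz <- spectra[[1]]$mz
    I <- t(vapply(spectra, function(s) s$intensity, numeric(length(mz))))
    cube <- c(base, list(mz = mz, intensity = I,
                         mz_range = range(mz)))
  } else {
    rng <- range(unlist(lapply(spectra, function(s) range(s$mz))))
    cube <- c(base, list(mz = NULL, intensity = NULL, spectra = spectra,
                         mz_range = rng))
  }
  structure(cube, class = "spectra_cube")
}

#' Resample a processed-mode cube onto a shared m/z grid
#'
#' @param cube a `spectra_cube` carrying per-pixel `spectra`.
#' @param axis target m/z axis; by default a grid uniform in ppm over the
#'   cube's m/z range.
#' @param step_ppm grid spacing in ppm for the default axis.
#' @return matrix-form `spectra_cube` on `axis` (linear interpolation; 0
#'   outside each pixel's support).
#' @export
cube_to_grid <- function(cube, axis = NULL, step_ppm = 5) {
  stopifnot(inherits(cube, "spectra_cube"))
  if (!is.null(cube$intensity)) return(cube)
  if (is.null(axis)) {
    r <- cube$mz_range
    n <- ceiling(log(r[2] / r[1]) / log1p(step_ppm * 1e-6))
    axis <- r[1] * (1 + step_ppm * 1e-6)^(0:n)
  }
  I <- t(vapply(cube$spectra, function(s) {
    if (length(s$mz) < 2) {
      out <- numeric(length(axis))
      if (length(s$mz) == 1) out[which.min(abs(axis - s$mz))] <- s$intensity
      return(out)
    }
    y <- stats::approx(s$mz, s$intensity, xout = axis, yleft = 0,
                       yright = 0)$y
    y[is.na(y)] <- 0
    y
  }, numeric(length(axis))))
  cube$mz <- axis
  cube$intensity <- I
  cube$spectra <- NULL
  cube
}
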