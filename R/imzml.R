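# Minimal imzML 1.1 IO: paired .imzML (mzML-flavoured XML) + .ibd binary.
# Processed mode is the canonical internal representation; continuous-mode
# files are accepted on read and converted. Only uncompressed 64-bit float
# arrays are written; 32/64-bit float and integer arrays are read.

#' Pixel grid of an MSI acquisition
#'
#' @param width,height raster dimensions in pixels.
#' @param coords data frame with integer columns `x`, `y` (0-based, x right,
#'   y down) listing the pixels present in the file.
#' @param pixel_size pixel edge length in micrometers (metadata only).
#' @return A `pixel_grid` object.
#' @export
pixel_grid <- function(width, height, coords, pixel_size = NA_real_) {
  stopifnot(is.data.frame(coords), all(c("x", "y") %in% names(coords)))
  coords <- data.frame(x = as.integer(coords$x), y = as.integer(coords$y))
  if (anyDuplicated(coords[c("x", "y")])) stop("duplicate pixel coordinates")
  if (any(coords$x < 0L | coords$x >= width | coords$y < 0L | coords$y >= height)) {
    stop("pixel coordinates outside [0, width) x [0, height)")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, coords = coords),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("Pixel grid: %d x %d, %d pixels present\n",
              x$width, x$height, nrow(x$coords)))
  invisible(x)
}

#' Construct an in-memory spectra collection
#'
#' The internal per-pixel peak-list container produced by [read_imzml()] and
#' consumed by [extract_ion_images()], [recalibrate()] and [write_imzml()].
#'
#' @param grid a [pixel_grid()].
#' @param mz,intensity lists of numeric vectors, one per row of
#'   `grid$coords`, with matching lengths per pixel.
#' @param mode `"processed"` or `"continuous"` (provenance only; storage is
#'   always per-pixel peak lists).
#' @return An `msi_spectra` object.
#' @export
msi_spectra <- function(grid, mz, intensity, mode = "processed") {
  n <- nrow(grid$coords)
  stopifnot(length(mz) == n, length(intensity) == n)
  lm <- lengths(mz); li <- lengths(intensity)
  if (any(lm != li)) stop("m/z and intensity lengths differ for some pixels")
  structure(list(grid = grid, mz = mz, intensity = intensity, mode = mode),
            class = "msi_spectra")
}

#' @export
print.msi_spectra <- function(x, ...) {
  cat(sprintf("MSI spectra: %d pixels on a %d x %d grid (%s mode), %d peaks total\n",
              nrow(x$grid$coords), x$grid$width, x$grid$height, x$mode,
              sum(lengths(x$mz))))
  invisible(x)
}

.IMZML_NS <- "http://psi.hupo.org/ms/mzml"

.imzml_binary_type <- function(cv_accessions) {
  if ("MS:1000523" %in% cv_accessions) list(what = "double", size = 8)
  else if ("MS:1000521" %in% cv_accessions) list(what = "double", size = 4)
  else if ("IMS:1000141" %in% cv_accessions) list(what = "integer", size = 4)
  else if ("IMS:1000142" %in% cv_accessions) list(what = "integer", size = 8)
  else stop("unsupported binary data type in imzML (no float/integer cvParam)")
}

#' Read an imzML file
#'
#' Parses the XML index, reads every spectrum's m/z and intensity arrays from
#' the paired `.ibd` binary, and returns an [msi_spectra()] collection plus
#' the populated [pixel_grid()]. Both processed- and continuous-mode files are
#' accepted; continuous mode is validated (all spectra share one m/z axis
#' length) and converted to per-pixel peak lists.
#'
#' @param path path to the `.imzML` file; the `.ibd` must sit next to it.
#' @return An `msi_spectra` object (grid in `$grid`).
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")
  if (!file.exists(ibd)) {
    stop("missing imzML binary file: ", ibd)
  }
  doc <- xml2::read_xml(path)
  ns <- c(mz = .IMZML_NS)

  # referenceable param groups: which group id is the m/z / intensity array,
  # and with what precision
  groups <- xml2::xml_find_all(doc, ".//mz:referenceableParamGroup", ns)
  mz_group <- int_group <- NULL
  mz_type <- int_type <- NULL
  for (g in groups) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "./mz:cvParam", ns), "accession")
    gid <- xml2::xml_attr(g, "id")
    if ("MS:1000514" %in% acc) { mz_group <- gid; mz_type <- .imzml_binary_type(acc) }
    if ("MS:1000515" %in% acc) { int_group <- gid; int_type <- .imzml_binary_type(acc) }
  }
  if (is.null(mz_group) || is.null(int_group)) {
    stop("imzML referenceableParamGroupList does not declare m/z and intensity arrays")
  }

  fc <- xml2::xml_find_first(doc, ".//mz:fileDescription/mz:fileContent", ns)
  fc_acc <- xml2::xml_attr(xml2::xml_find_all(fc, "./mz:cvParam", ns), "accession")
  mode <- if ("IMS:1000030" %in% fc_acc) "continuous" else "processed"

  ss <- xml2::xml_find_first(doc, ".//mz:scanSettings", ns)
  get_ss <- function(acc) {
    nd <- xml2::xml_find_first(
      ss, sprintf("./mz:cvParam[@accession='%s']", acc), ns)
    if (inherits(nd, "xml_missing")) NA_real_ else as.numeric(xml2::xml_attr(nd, "value"))
  }
  width <- get_ss("IMS:1000042"); height <- get_ss("IMS:1000043")
  px_size <- get_ss("IMS:1000046")

  spectra <- xml2::xml_find_all(doc, ".//mz:spectrumList/mz:spectrum", ns)
  n <- length(spectra)
  if (n == 0L) stop("imzML contains no spectra")

  xs <- ys <- integer(n)
  mz_off <- int_off <- numeric(n)
  mz_len <- int_len <- integer(n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    scan <- xml2::xml_find_first(sp, "./mz:scanList/mz:scan", ns)
    cvp <- xml2::xml_find_all(scan, "./mz:cvParam", ns)
    acc <- xml2::xml_attr(cvp, "accession"); val <- xml2::xml_attr(cvp, "value")
    xs[i] <- as.integer(val[match("IMS:1000050", acc)])
    ys[i] <- as.integer(val[match("IMS:1000051", acc)])
    for (bda in xml2::xml_find_all(sp, "./mz:binaryDataArrayList/mz:binaryDataArray", ns)) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./mz:referenceableParamGroupRef", ns), "ref")
      bacc <- xml2::xml_attr(xml2::xml_find_all(bda, "./mz:cvParam", ns), "accession")
      bval <- xml2::xml_attr(xml2::xml_find_all(bda, "./mz:cvParam", ns), "value")
      off <- as.numeric(bval[match("IMS:1000102", bacc)])
      len <- as.integer(bval[match("IMS:1000103", bacc)])
      if (identical(ref, mz_group)) { mz_off[i] <- off; mz_len[i] <- len }
      else if (identical(ref, int_group)) { int_off[i] <- off; int_len[i] <- len }
    }
  }
  if (any(mz_len != int_len)) stop("imzML spectrum with mismatched m/z/intensity array lengths")
  if (mode == "continuous" && length(unique(mz_len)) > 1L) {
    stop("inconsistent spectrum lengths in continuous-mode imzML")
  }

  con <- file(ibd, "rb")
  on.exit(close(con))
  read_arr <- function(off, len, type) {
    seek(con, where = off)
    readBin(con, what = type$what, n = len, size = type$size, endian = "little")
  }
  mz_list <- vector("list", n); int_list <- vector("list", n)
  for (i in seq_len(n)) {
    mz_list[[i]] <- read_arr(mz_off[i], mz_len[i], mz_type)
    int_list[[i]] <- read_arr(int_off[i], int_len[i], int_type)
  }

  # imzML scan positions are 1-based; internal convention is 0-based
  coords <- data.frame(x = xs - 1L, y = ys - 1L)
  if (is.na(width)) width <- max(coords$x) + 1L
  if (is.na(height)) height <- max(coords$y) + 1L
  grid <- pixel_grid(width, height, coords, pixel_size = px_size)
  msi_spectra(grid, mz_list, int_list, mode = mode)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an imzML file
#'
#' Writes a processed-mode imzML/ibd pair: per-pixel peak lists, uncompressed
#' little-endian 64-bit floats for both axes, so that
#' `read_imzml(write_imzml(x))` round-trips every (coordinate, m/z, intensity)
#' triple bit-identically. Pixels with empty peak lists are emitted with
#' zero-length arrays. The ibd UUID is derived from the binary payload (MD5),
#' so identical data yield byte-identical files.
#'
#' @param x an [msi_spectra()] object, or an [ion_image_stack()] (converted
#'   with [as_msi_spectra()]).
#' @param path output `.imzML` path; the `.ibd` is written alongside.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(x, path) {
  if (inherits(x, "ion_image_stack")) x <- as_msi_spectra(x)
  stopifnot(inherits(x, "msi_spectra"))
  if (!grepl("\\.imzML$", path)) path <- paste0(path, ".imzML")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  ibd <- sub("\\.imzML$", ".ibd", path)

  n <- nrow(x$grid$coords)
  lens <- lengths(x$mz)
  # ibd layout: 16-byte UUID, then per spectrum mz array followed by
  # intensity array
  body <- tempfile()
  con <- file(body, "wb")
  mz_off <- int_off <- numeric(n)
  pos <- 16
  for (i in seq_len(n)) {
    writeBin(as.double(x$mz[[i]]), con, size = 8, endian = "little")
    mz_off[i] <- pos; pos <- pos + 8 * lens[i]
    writeBin(as.double(x$intensity[[i]]), con, size = 8, endian = "little")
    int_off[i] <- pos; pos <- pos + 8 * lens[i]
  }
  close(con)
  md5 <- tools::md5sum(body)[[1]]
  uuid_bytes <- as.raw(strtoi(substring(md5, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  uuid_str <- paste0("{", substr(md5, 1, 8), "-", substr(md5, 9, 12), "-",
                     substr(md5, 13, 16), "-", substr(md5, 17, 20), "-",
                     substr(md5, 21, 32), "}")
  con <- file(ibd, "wb")
  writeBin(uuid_bytes, con)
  writeBin(readBin(body, "raw", n = file.size(body)), con)
  close(con)
  unlink(body)
  ibd_md5 <- tools::md5sum(ibd)[[1]]

  cv <- function(cvref, acc, name, value = NULL, unit = NULL) {
    s <- sprintf('<cvParam cvRef="%s" accession="%s" name="%s"', cvref, acc,
                 .xml_escape(name))
    if (!is.null(value)) s <- paste0(s, sprintf(' value="%s"', .xml_escape(as.character(value))))
    if (!is.null(unit)) {
      s <- paste0(s, sprintf(' unitCvRef="UO" unitAccession="%s" unitName="%s"',
                             unit[1], unit[2]))
    }
    paste0(s, "/>")
  }

  head <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    sprintf('<mzML xmlns="%s" version="1.1">', .IMZML_NS),
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="1.3.1" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" version="1.15" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" version="0.9.1" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription>',
    '<fileContent>',
    cv("MS", "MS:1000294", "mass spectrum"),
    cv("IMS", "IMS:1000031", "processed"),
    cv("IMS", "IMS:1000080", "universally unique identifier", uuid_str),
    cv("IMS", "IMS:1000090", "ibd MD5", toupper(ibd_md5)),
    '</fileContent>',
    '</fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", "MS:1000514", "m/z array", unit = c("MS:1000040", "m/z")),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", "MS:1000515", "intensity array", unit = c("MS:1000131", "number of detector counts")),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1">',
    '<software id="sisaflux" version="0.1.0"/>',
    '</softwareList>',
    '<scanSettingsList count="1">',
    '<scanSettings id="scansettings1">',
    cv("IMS", "IMS:1000042", "max count of pixels x", x$grid$width),
    cv("IMS", "IMS:1000043", "max count of pixels y", x$grid$height),
    cv("IMS", "IMS:1000046", "pixel size x",
       if (is.na(x$grid$pixel_size)) 1 else x$grid$pixel_size),
    cv("IMS", "IMS:1000047", "pixel size y",
       if (is.na(x$grid$pixel_size)) 1 else x$grid$pixel_size),
    '</scanSettings>',
    '</scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1">',
    '<dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="sisaflux">',
    cv("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod>',
    '</dataProcessing>',
    '</dataProcessingList>',
    '<run defaultInstrumentConfigurationRef="IC1" id="run1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">', n)
  )

  sp_xml <- character(n)
  for (i in seq_len(n)) {
    nb <- 8 * lens[i]
    sp_xml[i] <- paste0(
      sprintf('<spectrum defaultArrayLength="%d" id="spectrum=%d" index="%d">',
              lens[i], i, i - 1L),
      cv("MS", "MS:1000129", "negative scan"),
      '<scanList count="1">',
      cv("MS", "MS:1000795", "no combination"),
      '<scan>',
      cv("IMS", "IMS:1000050", "position x", x$grid$coords$x[i] + 1L),
      cv("IMS", "IMS:1000051", "position y", x$grid$coords$y[i] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv("IMS", "IMS:1000102", "external offset", sprintf("%.0f", mz_off[i])),
      cv("IMS", "IMS:1000103", "external array length", lens[i]),
      cv("IMS", "IMS:1000104", "external encoded length", nb),
      '<binary/>',
      '</binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv("IMS", "IMS:1000102", "external offset", sprintf("%.0f", int_off[i])),
      cv("IMS", "IMS:1000103", "external array length", lens[i]),
      cv("IMS", "IMS:1000104", "external encoded length", nb),
      '<binary/>',
      '</binaryDataArray>',
      '</binaryDataArrayList>',
      '</spectrum>')
  }

  tail <- c('</spectrumList>', '</run>', '</mzML>')
  writeLines(c(head, sp_xml, tail), path)
  invisible(path)
}
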