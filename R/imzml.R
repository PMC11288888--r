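# Minimal imzML 1.1 support: the XML index plus the external .ibd binary,
# continuous and processed modes, 32/64-bit float arrays. Coordinates are
# 1-based in imzML; this package works 0-based row-major and shifts on
# read/write.

#' In-memory MSI dataset
#'
#' @param coords integer matrix (n_pixels x 2) of 0-based (x, y) pixel
#'   coordinates.
#' @param mz shared m/z axis (numeric vector, continuous mode) or a list of
#'   per-spectrum m/z vectors (processed mode).
#' @param intensities list of per-spectrum intensity vectors.
#' @param mode `"continuous"` or `"processed"`.
#' @param pitch_um pixel pitch in microns.
#' @param mz_range acquisition m/z range, default `c(92, 700)` (the FTICR
#'   acquisition window the synthetic data emulates).
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensities, mode = c("continuous",
                        "processed"), pitch_um = 50, mz_range = c(92, 700)) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  n <- nrow(coords)
  stopifnot(ncol(coords) == 2L, length(intensities) == n)
  if (mode == "continuous") {
    stopifnot(is.numeric(mz))
    lens <- vapply(intensities, length, 1L)
    if (any(lens != length(mz)))
      stop2("continuous mode: every intensity array must match the shared ",
            "m/z axis length")
  } else {
    stopifnot(is.list(mz), length(mz) == n)
    if (any(vapply(mz, length, 1L) != vapply(intensities, length, 1L)))
      stop2("processed mode: per-spectrum m/z and intensity lengths differ")
  }
  structure(list(coords = coords, mz = mz, intensities = intensities,
                 mode = mode, pitch_um = pitch_um, mz_range = mz_range),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat("MSI dataset (", x$mode, " mode): ", nrow(x$coords), " pixels, ",
      if (x$mode == "continuous") length(x$mz) else "per-spectrum",
      " m/z channels, m/z range [", x$mz_range[1], ", ", x$mz_range[2],
      "]\n", sep = "")
  invisible(x)
}

msi_dims <- function(dataset) {
  c(max(dataset$coords[, 1L]) + 1L, max(dataset$coords[, 2L]) + 1L)
}

# deterministic pseudo-UUID derived from dataset shape + content
msi_uuid <- function(dataset) {
  key <- paste(nrow(dataset$coords), dataset$mode,
               signif(sum(unlist(dataset$intensities[1])), 10), sep = ":")
  with_seed(str_hash(key), as.raw(sample.int(256L, 16L, TRUE) - 1L))
}

uuid_string <- function(bytes) {
  h <- paste(format(bytes), collapse = "")
  paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
        substr(h, 17, 20), substr(h, 21, 32), sep = "-")
}

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

#' Write an MSI dataset as an imzML/ibd pair
#'
#' @param dataset an [msi_dataset()].
#' @param path output path (`.imzML` extension optional; the sibling `.ibd`
#'   is written next to it).
#' @param precision `"64"` or `"32"`-bit float binary arrays.
#' @return The `.imzML` path, invisibly.
#' @export
write_imzml <- function(dataset, path, precision = c("64", "32")) {
  precision <- match.arg(precision)
  stopifnot(inherits(dataset, "msi_dataset"))
  p <- imzml_paths(path)
  size <- if (precision == "64") 8L else 4L
  uuid <- msi_uuid(dataset)
  n <- nrow(dataset$coords)

  con <- file(p$ibd, "wb")
  writeBin(uuid, con)
  offset <- 16
  wr <- function(x) {
    writeBin(as.double(x), con, size = size, endian = "little")
    off <- offset
    offset <<- offset + length(x) * size
    off
  }
  mz_meta <- vector("list", n)
  int_meta <- vector("list", n)
  if (dataset$mode == "continuous") {
    shared_off <- wr(dataset$mz)
    for (i in seq_len(n)) {
      mz_meta[[i]] <- c(shared_off, length(dataset$mz))
      int_meta[[i]] <- c(wr(dataset$intensities[[i]]),
                         length(dataset$intensities[[i]]))
    }
  } else {
    for (i in seq_len(n)) {
      mz_meta[[i]] <- c(wr(dataset$mz[[i]]), length(dataset$mz[[i]]))
      int_meta[[i]] <- c(wr(dataset$intensities[[i]]),
                         length(dataset$intensities[[i]]))
    }
  }
  close(con)
  md5 <- unname(tools::md5sum(p$ibd))

  mode_cv <- if (dataset$mode == "continuous")
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>'
  else
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>'
  prec_acc <- if (precision == "64") "MS:1000523" else "MS:1000521"
  prec_name <- if (precision == "64") "64-bit float" else "32-bit float"
  dims <- msi_dims(dataset)

  spectrum_xml <- function(i) {
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, int_meta[[i]][2],
      dataset$coords[i, 1L] + 1L, dataset$coords[i, 2L] + 1L,
      mz_meta[[i]][2], mz_meta[[i]][2] * size, mz_meta[[i]][1],
      int_meta[[i]][2], int_meta[[i]][2] * size, int_meta[[i]][1])
  }

  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    mode_cv,
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', uuid_string(uuid)),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>', toupper(md5)),
    '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>', prec_acc, prec_name),
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>', prec_acc, prec_name),
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="sw1" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
    '</software></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', dims[1]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', dims[2]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>', dataset$pitch_um),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="sw1">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="dp1">', n),
    vapply(seq_len(n), spectrum_xml, ""),
    '</spectrumList></run>',
    '</mzML>'
  )
  writeLines(xml, p$xml)
  invisible(p$xml)
}

#' Read an imzML/ibd pair
#'
#' Supports continuous and processed binary modes with uncompressed 32- or
#' 64-bit float arrays. Coordinates are normalized to 0-based. The ibd UUID
#' is checked against the XML; array reads are bounds-checked against the ibd
#' size so truncation is reported with the offending byte offset.
#'
#' @param path `.imzML` file path (sibling `.ibd` required).
#' @param check_md5 verify the ibd MD5 checksum recorded in the XML.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, check_md5 = FALSE) {
  p <- imzml_paths(path)
  if (!file.exists(p$xml)) stop2("imzML file not found: ", p$xml)
  if (!file.exists(p$ibd))
    stop2("missing ibd file: ", p$ibd, " (imzML requires the sibling binary)")
  doc <- xml2::read_xml(p$xml)
  # namespace-aware queries (stripping namespaces walks every node and is
  # prohibitively slow on files with many spectra)
  nss <- xml2::xml_ns(doc)
  px <- if ("d1" %in% names(nss)) "d1:" else ""
  q <- function(path) {
    parts <- strsplit(path, "/", fixed = TRUE)[[1]]
    paste0(".//", paste(paste0(px, parts), collapse = "/"))
  }
  cv <- function(node, acc)
    xml2::xml_attr(xml2::xml_find_first(
      node, sprintf("%s[@accession='%s']", q("cvParam"), acc)), "value")

  fc <- xml2::xml_find_first(doc, q("fileDescription/fileContent"))
  mode <- if (!is.na(cv(fc, "IMS:1000030"))) "continuous"
          else if (!is.na(cv(fc, "IMS:1000031"))) "processed"
          else stop2("imzML mode (continuous/processed) not declared")
  uuid_xml <- gsub("[{}-]", "", cv(fc, "IMS:1000080"))

  ibd_size <- file.info(p$ibd)$size
  con <- file(p$ibd, "rb")
  on.exit(close(con))
  uuid_ibd <- paste(format(readBin(con, "raw", 16L)), collapse = "")
  if (!is.na(uuid_xml) && nzchar(uuid_xml) &&
      tolower(uuid_xml) != tolower(uuid_ibd))
    stop2("ibd UUID mismatch: XML declares ", uuid_xml, ", ibd holds ",
          uuid_ibd)
  if (check_md5) {
    md5_xml <- cv(fc, "IMS:1000090")
    if (!is.na(md5_xml) &&
        tolower(md5_xml) != tolower(unname(tools::md5sum(p$ibd))))
      stop2("ibd MD5 checksum mismatch")
  }

  # per-array precision from the referenceable param groups
  grp_size <- function(id) {
    g <- xml2::xml_find_first(doc,
          sprintf("%s[@id='%s']", q("referenceableParamGroup"), id))
    if (!is.na(cv(g, "MS:1000523"))) 8L
    else if (!is.na(cv(g, "MS:1000521"))) 4L
    else stop2("unsupported binary data type in param group '", id,
               "' (only 32/64-bit float supported)")
  }
  sizes <- c(mzArray = grp_size("mzArray"),
             intensityArray = grp_size("intensityArray"))

  # vectorized metadata extraction in document order; descendant-axis XPath
  # with leaf predicates only (deep double-descendant queries degrade badly
  # on files with many spectra)
  grab <- function(path, acc)
    xml2::xml_attr(xml2::xml_find_all(doc,
      sprintf("%s[@accession='%s']", q(path), acc)), "value")
  n <- length(xml2::xml_find_all(doc, q("spectrumList/spectrum")))
  if (n == 0L) stop2("imzML contains no spectra")
  pos_x <- as.integer(grab("scan/cvParam", "IMS:1000050")) - 1L
  pos_y <- as.integer(grab("scan/cvParam", "IMS:1000051")) - 1L
  # binary-array fields arrive interleaved (2 per spectrum); the ref
  # sequence tells which is the m/z and which the intensity array
  refs <- xml2::xml_attr(xml2::xml_find_all(
    doc, q("binaryDataArray/referenceableParamGroupRef")), "ref")
  offs <- as.numeric(grab("binaryDataArray/cvParam", "IMS:1000102"))
  lens <- as.integer(grab("binaryDataArray/cvParam", "IMS:1000103"))
  if (length(pos_x) != n || length(refs) != 2L * n ||
      length(offs) != 2L * n || length(lens) != 2L * n)
    stop2("imzML spectrum metadata incomplete")
  meta <- list(
    mzArray = list(offset = offs[refs == "mzArray"],
                   len = lens[refs == "mzArray"]),
    intensityArray = list(offset = offs[refs == "intensityArray"],
                          len = lens[refs == "intensityArray"]))
  if (any(vapply(meta, function(m) length(m$offset) != n, TRUE)))
    stop2("imzML spectrum metadata incomplete")
  coords <- cbind(pos_x, pos_y)

  read_array <- function(offset, len, size) {
    end <- offset + len * size
    if (end > ibd_size)
      stop2("truncated ibd: array at byte offset ", offset, " needs ", end,
            " bytes but file has ", ibd_size)
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = len, size = size, endian = "little")
  }

  mz_list <- vector("list", n)
  int_list <- vector("list", n)
  shared_mz <- NULL
  for (i in seq_len(n)) {
    m <- meta$mzArray
    if (mode == "continuous") {
      # continuous mode shares one m/z block; read it once
      if (is.null(shared_mz))
        shared_mz <- read_array(m$offset[i], m$len[i], sizes[["mzArray"]])
      mz_list[[i]] <- shared_mz
    } else {
      mz_list[[i]] <- read_array(m$offset[i], m$len[i], sizes[["mzArray"]])
    }
    it <- meta$intensityArray
    int_list[[i]] <- read_array(it$offset[i], it$len[i],
                                sizes[["intensityArray"]])
  }

  pitch <- as.numeric(cv(doc, "IMS:1000046"))
  if (is.na(pitch)) pitch <- 50
  if (mode == "continuous") {
    lens <- vapply(mz_list, length, 1L)
    if (length(unique(lens)) != 1L)
      stop2("continuous mode declared but spectra have differing m/z lengths")
    mz <- mz_list[[1]]
  } else {
    mz <- mz_list
  }
  rng <- range(unlist(mz_list[1]))
  msi_dataset(coords, mz, int_list, mode = mode, pitch_um = pitch,
              mz_range = c(min(92, floor(rng[1])), max(700, ceiling(rng[2]))))
}
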