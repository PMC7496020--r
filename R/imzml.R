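#' Write an MSI dataset to imzML
#'
#' Writes processed-mode centroid imzML: an XML index file plus the binary
#' `.ibd` companion holding 64-bit little-endian m/z and intensity arrays.
#' Output is byte-identical for identical input, so simulated datasets
#' round-trip deterministically.
#'
#' @param ds An [msi_dataset()].
#' @param path Path of the `.imzML` file to write; the `.ibd` companion is
#'   written next to it.
#' @param uuid Optional 32-hex-character identifier; derived from the data
#'   when omitted (deterministically, so rewrites are identical).
#' @return `path`, invisibly.
#' @export
write_imzml <- function(ds, path, uuid = NULL) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (is.null(uuid)) uuid <- data_uuid(ds)
  stopifnot(grepl("^[0-9a-f]{32}$", uuid))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (ibd_path == path) ibd_path <- paste0(path, ".ibd")

  n <- nrow(ds$coords)
  counts <- integer(n)
  tab <- tabulate(ds$peaks$pixel, nbins = n)
  counts <- tab
  # per-pixel slice bounds into the ordered peak table
  ends <- cumsum(counts)
  starts <- ends - counts + 1L

  # ibd: 16-byte uuid, then per pixel mz array followed by intensity array
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)),
                         base = 16L)), con)
  offset <- 16
  mz_off <- int_off <- numeric(n)
  for (i in seq_len(n)) {
    mz_off[i] <- offset
    if (counts[i] > 0L) {
      writeBin(ds$peaks$mz[starts[i]:ends[i]], con, size = 8,
               endian = "little")
    }
    offset <- offset + 8 * counts[i]
    int_off[i] <- offset
    if (counts[i] > 0L) {
      writeBin(ds$peaks$intensity[starts[i]:ends[i]], con, size = 8,
               endian = "little")
    }
    offset <- offset + 8 * counts[i]
  }

  spectra <- sprintf(
    paste0(
      '      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
      '        <scanList count="1">\n',
      '          <scan>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>'
    ),
    seq_len(n) - 1L, seq_len(n), counts,
    ds$coords$x + 1L, ds$coords$y + 1L,
    mz_off, counts, 8 * counts,
    int_off, counts, 8 * counts
  )

  pol_cv <- if (ds$polarity == "+") {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  }
  header <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
      '  <fileDescription>\n',
      '    <fileContent>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>\n',
      '      %s\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
      '    </fileContent>\n',
      '  </fileDescription>\n',
      '  <referenceableParamGroupList count="2">\n',
      '    <referenceableParamGroup id="mzArray">\n',
      '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
      '    </referenceableParamGroup>\n',
      '    <referenceableParamGroup id="intensityArray">\n',
      '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
      '    </referenceableParamGroup>\n',
      '  </referenceableParamGroupList>\n',
      '  <scanSettingsList count="1">\n',
      '    <scanSettings id="scan1">\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>\n',
      '    </scanSettings>\n',
      '  </scanSettingsList>\n',
      '  <run id="%s">\n',
      '    <spectrumList count="%d">'
    ),
    pol_cv, uuid, ds$pixel_size, ds$pixel_size, ds$modality, n
  )
  footer <- "    </spectrumList>\n  </run>\n</mzML>\n"
  writeLines(c(header, spectra, footer), path, sep = "\n")
  invisible(path)
}

# Deterministic 32-hex identifier from the numeric content (FNV-style mix
# over a digest of coordinates and intensities; not cryptographic).
data_uuid <- function(ds) {
  v <- c(ds$coords$x, ds$coords$y, round(ds$peaks$mz * 1e4) %% 1e6,
         round(ds$peaks$intensity * 1e3) %% 1e6)
  idx <- (seq_along(v) - 1L) %% 8L + 1L
  h <- vapply(1:8, function(i) {
    vi <- v[idx == i]
    if (!length(vi)) return(0)
    sum((vi %% 65521) * (seq_along(vi) %% 251 + 1)) %% 65536
  }, numeric(1))
  paste(sprintf("%04x", as.integer(h)), collapse = "")
}

#' Read a processed-mode centroid imzML file
#'
#' Counterpart of [write_imzml()]: continuous-mode files are rejected and a
#' missing `.ibd` companion is reported with the expected path.
#'
#' @param path `.imzML` file path.
#' @param pixel_size Override for pixel size (um) when the file does not
#'   record one.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, pixel_size = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed imzML XML in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  mode_processed <- length(xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='IMS:1000031']")) > 0
  mode_continuous <- length(xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='IMS:1000030']")) > 0
  if (mode_continuous || !mode_processed) {
    stop("only processed-mode (per-pixel m/z axis) imzML is supported; '",
         path, "' is continuous-mode or unmarked", call. = FALSE)
  }
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) {
    stop("missing .ibd companion: expected '", ibd_path, "'", call. = FALSE)
  }
  polarity <- if (length(xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='MS:1000129']"))) "-" else "+"
  px <- xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000046']")
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(px, "xml_missing")) 1 else
      as.numeric(xml2::xml_attr(px, "value"))
  }
  modality <- xml2::xml_attr(xml2::xml_find_first(doc, "//run"), "id")
  if (is.na(modality)) modality <- "MALDI"

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  get_num <- function(xpath) {
    as.numeric(xml2::xml_attr(xml2::xml_find_all(spectra, xpath), "value"))
  }
  x <- get_num(".//cvParam[@accession='IMS:1000050']")
  y <- get_num(".//cvParam[@accession='IMS:1000051']")
  arrays <- xml2::xml_find_all(spectra, ".//binaryDataArray")
  refs <- xml2::xml_attr(
    xml2::xml_find_first(arrays, "./referenceableParamGroupRef"), "ref")
  offs <- as.numeric(xml2::xml_attr(
    xml2::xml_find_first(arrays, "./cvParam[@accession='IMS:1000102']"),
    "value"))
  lens <- as.integer(xml2::xml_attr(
    xml2::xml_find_first(arrays, "./cvParam[@accession='IMS:1000103']"),
    "value"))
  is_mz <- refs == "mzArray"
  n <- length(spectra)
  stopifnot(sum(is_mz) == n, sum(!is_mz) == n)

  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  read_arr <- function(off, len) {
    if (len == 0L) return(numeric(0))
    seek(con, where = off)
    readBin(con, what = "double", n = len, size = 8, endian = "little")
  }
  mz_off <- offs[is_mz]; mz_len <- lens[is_mz]
  in_off <- offs[!is_mz]; in_len <- lens[!is_mz]
  mzs <- lapply(seq_len(n), function(i) read_arr(mz_off[i], mz_len[i]))
  ins <- lapply(seq_len(n), function(i) read_arr(in_off[i], in_len[i]))

  coords <- data.frame(x = as.integer(x) - 1L, y = as.integer(y) - 1L)
  peaks <- data.frame(
    pixel = rep.int(seq_len(n), mz_len),
    mz = unlist(mzs, use.names = FALSE),
    intensity = unlist(ins, use.names = FALSE)
  )
  msi_dataset(coords, peaks, pixel_size = pixel_size, polarity = polarity,
              modality = modality)
}
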