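# Minimal mzML support.
#
# The usual R route to mzML (mzR) is not available in this toolchain, so a
# small reader/writer is provided covering what native-MS profile data needs:
# MS1 spectra, 32/64-bit float binary arrays, zlib or no compression. This is
# deliberately not a general mzML implementation.

decode_binary_array <- function(b64, precision, compressed, n_expected) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (compressed)
    raw <- memDecompress(raw, type = "gzip")
  size <- if (precision == 64L) 8L else 4L
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}

read_mzml_scans <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  scans <- list()
  for (sp in specs) {
    ms_level <- xml2::xml_find_first(
      sp, "./cvParam[@accession='MS:1000511']")
    if (!inherits(ms_level, "xml_missing") &&
        xml2::xml_attr(ms_level, "value") != "1") next
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- NULL; it <- NULL
    for (arr in arrays) {
      cvs <- xml2::xml_find_all(arr, "./cvParam")
      acc <- xml2::xml_attr(cvs, "accession")
      precision <- if ("MS:1000523" %in% acc) 64L
                   else if ("MS:1000521" %in% acc) 32L
                   else stop("unsupported binary precision in ", path)
      compressed <- "MS:1000574" %in% acc
      b64 <- xml2::xml_text(xml2::xml_find_first(arr, "./binary"))
      vals <- decode_binary_array(b64, precision, compressed)
      if ("MS:1000514" %in% acc) mz <- vals
      if ("MS:1000515" %in% acc) it <- vals
    }
    if (is.null(mz) || is.null(it))
      stop("spectrum without m/z or intensity array in ", path)
    scans[[length(scans) + 1L]] <- list(mz = mz, intensity = it)
  }
  scans
}

encode_binary_array <- function(x, precision = 64L) {
  raw <- writeBin(as.numeric(x), raw(), size = if (precision == 64L) 8L else 4L,
                  endian = "little")
  jsonlite::base64_enc(raw)
}

#' Write a spectrum to a minimal mzML file
#'
#' Emits a single-scan (or multi-scan) MS1 mzML document with uncompressed
#' 64-bit float arrays, readable by [read_spectrum()] and by standard
#' proteomics tooling.
#'
#' @param spec A `spectrum`, or a list of `spectrum` objects (one scan each).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spec, path) {
  scans <- if (inherits(spec, "spectrum")) list(spec) else spec
  spectra_xml <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    n <- length(s$mz)
    mz_b64 <- encode_binary_array(s$mz)
    it_b64 <- encode_binary_array(s$intensity)
    paste0(
      sprintf('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n', i - 1L, i, n),
      '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '        <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray>\n',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>\n',
      '            <binary>', mz_b64, '</binary>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray>\n',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>\n',
      '            <binary>', it_b64, '</binary>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>\n')
  }, character(1L))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <run id="run1">\n',
    sprintf('    <spectrumList count="%d">\n', length(scans)),
    paste(spectra_xml, collapse = ""),
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  writeLines(doc, path, sep = "")
  invisible(path)
}
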