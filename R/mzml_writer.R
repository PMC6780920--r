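## Minimal deterministic mzML 1.1 writer for fixtures and channel export.
## Arrays are uncompressed 64-bit little-endian base64; no timestamps or
## other run-dependent content, so identical inputs give byte-identical
## files.

.b64dbl <- function(x)
    gsub("[\r\n]", "",
         jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L,
                                       endian = "little")))

.mzmlSpectrum <- function(idx, scanId, mz, intensity, rtMin, msLevel,
                          energy, polarity) {
    polcv <- if (polarity == "negative")
        '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
    else
        '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
    ce <- suppressWarnings(as.numeric(energy))
    prec <- if (msLevel >= 2L && !is.na(ce)) sprintf('
      <precursorList count="1"><precursor>
        <isolationWindow><cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="400.0" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/></isolationWindow>
        <selectedIonList count="1"><selectedIon><cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="400.0" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/></selectedIon></selectedIonList>
        <activation>
          <cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation" value=""/>
          <cvParam cvRef="MS" accession="MS:1000045" name="collision energy" value="%s" unitCvRef="UO" unitAccession="UO:0000266" unitName="electronvolt"/>
        </activation>
      </precursor></precursorList>' , energy) else ""
    bmz <- .b64dbl(mz); bint <- .b64dbl(intensity)
    sprintf('
    <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>
      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
      %s
      <scanList count="1">
        <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>
        <scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.10f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan>
      </scanList>%s
      <binaryDataArrayList count="2">
        <binaryDataArray encodedLength="%d">
          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
          <binary>%s</binary>
        </binaryDataArray>
        <binaryDataArray encodedLength="%d">
          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
          <binary>%s</binary>
        </binaryDataArray>
      </binaryDataArrayList>
    </spectrum>',
    idx - 1L, scanId, length(mz), msLevel, polcv, rtMin, prec,
    nchar(bmz), bmz, nchar(bint), bint)
}

#' Write a ScanSet to mzML
#'
#' Serializes a [ScanSet-class] (or [ScanChannel-class]) as centroid-mode
#' mzML 1.1 with uncompressed 64-bit arrays. The output carries no
#' timestamps: the same object always produces a byte-identical file, which
#' is what makes simulated fixtures reproducible. Collision energies are
#' written as the standard activation cvParam on MS2 scans, so the file
#' re-reads with the same energy labels (numeric labels only).
#'
#' @param x a [ScanSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMzML <- function(x, path) {
    stopifnot(is(x, "ScanSet"))
    h <- scanHeader(x)
    pk <- scanPeaks(x)
    specs <- vapply(seq_len(nrow(h)), function(i) {
        .mzmlSpectrum(i, h$scanId[i], pk[[i]][, 1], pk[[i]][, 2],
                      h$rt[i], h$msLevel[i], h$energy[i], h$polarity[i])
    }, character(1))
    doc <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
  </cvList>
  <fileDescription><fileContent>
    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
    <cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>
  </fileContent></fileDescription>
  <softwareList count="1"><software id="metaif" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="metaif"/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">
    <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>
  </instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="metaif">
    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
  </processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="dp1">%s
    </spectrumList>
  </run>
</mzML>', nrow(h), paste(specs, collapse = ""))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(doc), con)   # bytewise, no platform newline rewriting
    invisible(path)
}
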