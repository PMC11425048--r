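# Shared fixture builders: tiny spectra, files and peptide tables built in
# code at test time.

make_spectrum <- function(id, mz, intensity, precursor_mz = 500, charge = 2L,
                          rt = 60) {
  psmsearch:::new_raw_spectrum(id, precursor_mz, charge, rt, mz, intensity)
}

# a spectrum that is exactly the 1+/2+ b/y ladder of a peptide
ladder_spectrum <- function(id, peptide, deltas = NULL, charge = 2L, rt = 60,
                            intensity = 100) {
  fr <- fragment_ions(peptide, deltas,
                      charges = if (charge >= 2L) c(1L, 2L) else 1L)
  mz <- c(unlist(fr$b, use.names = FALSE), unlist(fr$y, use.names = FALSE))
  M <- peptide_mass(peptide, deltas)
  make_spectrum(id, mz, rep(intensity, length(mz)),
                precursor_mz = (M + charge * PROTON_MASS) / charge,
                charge = charge, rt = rt)
}

write_tiny_mgf <- function(path, blocks) {
  writeLines(unlist(blocks), path)
  path
}

random_peptide <- function(len) {
  paste(sample(names(AA_MONO), len, replace = TRUE), collapse = "")
}

# peptide table in the build_peptide_db layout, from raw sequences
peptide_table <- function(peptides, is_decoy = rep(FALSE, length(peptides))) {
  data.frame(peptide = peptides,
             missed_cleavages = 0L,
             proteins = ifelse(is_decoy, "DECOY_P1", "P1"),
             shared = FALSE,
             is_decoy = is_decoy,
             n_var_sites = 0L)
}

# minimal uncompressed mzML document with 64-bit little-endian peak arrays
write_tiny_mzml <- function(path, scans) {
  b64 <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                   size = 8, endian = "little"))
  enc <- function(x) {
    e <- b64(x)
    sprintf('<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/><cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>%%s<binary>%s</binary></binaryDataArray>',
            nchar(e), e)
  }
  one <- function(idx, sc) {
    prec <- if (!is.null(sc$precursor_mz)) sprintf(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon><cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>%s</selectedIon></selectedIonList></precursor></precursorList>',
      sc$precursor_mz,
      if (!is.null(sc$charge)) sprintf('<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>', sc$charge) else ""
    ) else ""
    mzarr <- sprintf(enc(sc$mz), '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>')
    intarr <- sprintf(enc(sc$intensity), '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>')
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d"><cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/><cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/><scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.4f" unitAccession="UO:0000010" unitName="second"/></scan></scanList>%s<binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>',
            idx, idx + 1L, length(sc$mz), sc$ms_level, sc$rt, prec, mzarr, intarr)
  }
  body <- paste(vapply(seq_along(scans), function(i) one(i - 1L, scans[[i]]),
                       character(1L)), collapse = "\n")
  doc <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="x"/><cv id="UO" fullName="UO" URI="x"/></cvList>
<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/></fileContent></fileDescription>
<softwareList count="1"><software id="sw" version="1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="sim"/></software></softwareList>
<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model"/></instrumentConfiguration></instrumentConfigurationList>
<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/></processingMethod></dataProcessing></dataProcessingList>
<run id="run" defaultInstrumentConfigurationRef="ic" defaultDataProcessingRef="dp">
<spectrumList count="%d" defaultDataProcessingRef="dp">
%s
</spectrumList></run></mzML>', length(scans), body)
  writeLines(doc, path)
  path
}

strip_psm_attrs <- function(x) {
  attr(x, "index") <- NULL
  attr(x, "peptides") <- NULL
  attr(x, "peptide_psms") <- NULL
  as.data.frame(x)
}

# both best-PSM tables (per spectrum and per peptide) as plain data.frames
psm_pair <- function(x) {
  list(spectrum = strip_psm_attrs(x),
       peptide = strip_psm_attrs(attr(x, "peptide_psms")))
}
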