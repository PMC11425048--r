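Package: psmsearch
Title: Full-Database Peptide-Spectrum Matching with an Inverted Spectrum Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A peptide search engine for data-dependent acquisition (DDA)
    proteomics that searches every in-silico digested, variably modified
    peptide of a protein database against every MS2 spectrum, without any
    precursor mass tolerance. Experimental spectra are discretized on an
    optimal-width m/z bin grid and stored in an inverted index (bin to
    spectrum postings), so memory scales with the number of spectra rather
    than with the candidate peptide space. Candidates are scored with an
    X!Tandem-style hyperscore and a Comet-style fast cross-correlation, and
    validated per run by a learned stage: a four-branch retention-time
    regressor over sequence-composition features and a three-layer
    discriminant network, followed by target-decoy q-values at the PSM,
    peptide and protein levels. Includes a synthetic DDA run generator with
    known ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
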