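Package: emvprofiler
Title: Proteomic Characterization of Brain Endothelial Extracellular Microvesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for label-free proteomic profiling of
    extracellular microvesicles (EMVs) released by brain endothelial cells.
    Implements target-decoy false-positive-rate filtering of peptide-spectrum
    matches with constrained threshold optimization, MS1 signal-fraction
    quantification and exact Mann-Whitney group comparison, SDS-PAGE gel-band
    molecular-weight concordance analysis, marker-catalog overlap and
    permutation-based category over-representation, in-silico surface
    interactomics between vesicle and target-cell surface proteomes, and
    targeted MRM transition extraction with relative quantification. A
    synthetic-data generator with planted ground truth makes every stage
    testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
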