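Package: peakdecoder
Title: Target-Decoy Scoring and Error Rate Estimation for LC-IM-MS DIA
    Metabolomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores co-elution and co-mobility of precursor/fragment
    peak-groups in liquid chromatography - ion mobility - mass spectrometry
    (LC-IM-MS) data acquired with data-independent acquisition (DIA).
    Decoy peak-groups are generated directly from deconvoluted experimental
    features by pairing and fragment m/z swapping, a radial-kernel support
    vector machine is trained on seven co-elution descriptors, and the
    calibrated target-class probability (the PeakDecoder score) is mapped
    to an estimated false-discovery rate without requiring annotated
    spectral libraries.  Query metabolites from an RT-CCS-MS/MS library are
    annotated with explicit mass, retention-time and collision-cross-section
    error cutoffs.  Includes readers for feature-alignment exports,
    targeted-extraction XIC reports and NIST MSP libraries, and a synthetic
    data generator for end-to-end validation with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
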