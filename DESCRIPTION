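Package: msiresponse
Title: Validating MALDI Mass Spectrometry Imaging of Lipids Against Absolute Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate MALDI and MALDI-2 mass spectrometry imaging
    (MSI) of membrane lipids against absolute quantification by LC-MS.
    Computes adduct-resolved theoretical m/z values for glycerophospholipids
    and sulfatides, enumerates near-isobaric ion pairs, extracts ppm-tolerant
    ion images from imzML data, segments tissue by spectral k-means,
    quantifies lipids by internal-standard external calibration of extracted
    ion chromatogram peak areas, converts amounts to tissue molar
    concentration via dissected region geometry, and derives tissue-type- and
    modality-specific signal response factors (signal intensity per mol).
    Ground-truthed synthetic MSI and LC-MS generators make every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    xml2,
    yaml,
    jsonlite,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
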