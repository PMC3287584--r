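Package: prodis
Title: Proteomics Experiment Data Management with Provenance Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-project data-management engine for proteomics
    laboratories working with liquid chromatography, two-dimensional gel
    electrophoresis and mass spectrometry. Experiments are stored in an
    embedded relational database with a managed file store, linked into a
    provenance graph so samples can be traced from protein extraction to
    identification, and rendered as experiment trees in reports. Includes
    parsers for instrument peak-list dialects (pkl, MGF, mzML, mzXML,
    mzData), 2D-gel spot quantitation tables, LC peak tables and search
    engine result exports; MALDI target-plate mapping of wells to gel
    spots; minimum-information (MIAPE-style) completeness checking; role
    based access control with an audit trail; and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    digest,
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    xml2
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
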