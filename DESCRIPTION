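Package: ms2forest
Title: Random-Forest Prediction of Peptide MS2 Fragment-Ion Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting tandem mass spectrometry (MS2) peak
    intensities from peptide sequences. Parses PTM-annotated peptides in the
    'H-P-OH' grammar, computes theoretical m/z values for the b+, y+, b++ and
    y++ fragment-ion series, trains per-fragmentation-method and
    per-precursor-charge random-forest intensity regressors from annotated
    spectra, writes predicted spectra to Mascot Generic Format (MGF) or CSV,
    and evaluates predictions against observations by per-PSM Pearson
    correlation. A synthetic-data module generates peptides and spectra with
    a known intensity rule so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    ranger,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
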