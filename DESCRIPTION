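Package: microreflect
Title: Microreflectance Thickness Metrology for Thin Biomaterial Films on Si/SiO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optical thickness metrology for thin protein (and other
    transparent biomaterial) films deposited on oxidized silicon wafers.
    Simulates normal-incidence multilayer reflectance with the
    transfer-matrix method, converts paired film/substrate microreflectance
    spectra into optical contrast, inverts contrast spectra to film
    thickness by least squares, builds an apparent-color thickness guide
    through CIE colorimetry, segments bright-field film micrographs into
    thickness regions by k-means clustering to estimate film volume, and
    fits linear thickness-concentration calibration curves with confidence
    intervals. Includes synthetic-data generators so the whole pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
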