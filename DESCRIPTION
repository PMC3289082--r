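Package: msCharge
Title: Unsupervised Charge-State Assignment for Low-Resolution CID Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns precursor charge states (+2 versus +3) to low-resolution
    collision-induced dissociation (CID) tandem mass spectra without training
    data. Four spectrum-derived features -- the complementary-pair count
    difference, the complementary-pair intensity-ratio difference, the doubly
    charged intensity above the precursor m/z, and a basic-site pseudo-count --
    are computed from b/y fragment-ion mass arithmetic and clustered with a
    two-component spherical Gaussian mixture model fitted by
    expectation-maximisation. Includes an MGF reader/writer, ROC/AUC
    evaluation, and a synthetic ion-trap CID spectrum generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
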