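Package: npuptake
Title: Label-Free Quantification of Nanoparticle Uptake from 3D Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cellular uptake of metal nanoparticles from
    multichannel 3D confocal stacks in which particles are detected label-free
    in reflection mode and cells by fluorescence. Provides 3D Gaussian
    filtering, global (Otsu) thresholding, 3D connected-component labeling and
    per-object measurement (centroid, volume, surface, integrated density);
    centroid-in-cell assignment of particles; per-cell and field-of-view
    concentration summaries with time-course binning; discrimination of
    particle aggregates by a Gaussian mixture with means constrained to
    integer multiples of the primary-particle intensity; and a synthetic stack
    generator with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    withr,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
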