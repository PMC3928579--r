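Package: onhbga
Title: Optic Nerve Head Morphometry and Glaucoma Advancement Scoring from OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic analysis of 3-D optical coherence tomography (OCT)
    volumes of the optic nerve head. Segments the retinal pigment epithelium
    (RPE), inner limiting membrane (ILM) and retinal nerve fibre layer (RNFL)
    boundaries per B-scan, derives the optic disk and cup en-face geometry,
    samples the peripapillary RNFL thickness on a polar annulus, and combines
    three normalized biomorphological features into a single glaucoma
    advancement score (BGA) with a linear conversion to the expected
    perimetric mean defect. Includes a synthetic phantom generator with
    analytic ground truth, open-format readers and writers replacing the
    vendor container, an exploratory factor-analysis module for morphometric
    feature tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    graphics,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
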