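Package: regqc
Title: Standardized Visual Quality Control for Brain Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for a standardized visual quality-control (QC) protocol for
    the registration of structural T1 brain images to a stereotaxic template.
    Builds the brain-outline landmark mask ("confidence interval" shell) by
    millimetre-calibrated morphology, renders the nine-slice template/individual
    mosaic pair with a red landmark overlay, converts rater tag spheres into
    three-level ratings (OK / Maybe / Fail), aggregates raters into consensus
    panels by plurality with worst-category tie-breaking, quantifies inter-rater
    agreement (weighted Cohen's kappa, per-category Sorensen-Dice, Landis-Koch
    bands), and performs kappa sample-size and power analysis after Flack,
    Afifi, Lachenbruch and Schouten (1988). A phantom-volume generator and a
    crowdsourced-rater simulator make the whole pipeline testable without
    access to real imaging or rating data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'volume.R'
    'edt.R'
    'landmarks.R'
    'mosaic.R'
    'rating.R'
    'ratingtable.R'
    'consensus.R'
    'agreement.R'
    'lp.R'
    'kappa-power.R'
    'simulate.R'
    'protocol.R'
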