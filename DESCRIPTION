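Package: cazquant
Title: Quantitative Single-Molecule Localization Analysis of Active-Zone Cytomatrix Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of single-molecule localization
    microscopy (dSTORM) data of the presynaptic active-zone cytomatrix (CAZ).
    Implements density-gradient clustering of localization point patterns with
    minimum-area enclosing-ellipse cluster descriptors and grouping of clusters
    into CAZ-units, rendering and mask-based segmentation of localization data,
    localization-precision estimation (pooled isolated-emitter histograms and
    nearest-neighbour analysis), protein copy-number calibration from antibody
    titration series via logistic fits and a molecules-per-localization
    conversion factor with propagated uncertainties, radial density profiles,
    and constrained synaptic vesicle-pool models of short-term plasticity
    (depression during high-frequency trains with biphasic recovery) including
    simulation and three-parameter fitting. A synthetic-data module generates
    localization fields, titration experiments, isolated-antibody data and
    evoked-current trains with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
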