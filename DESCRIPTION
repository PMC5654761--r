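Package: eidhotspots
Title: Reporting-Effort-Corrected Mapping of Zoonotic Disease Emergence Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for modelling the global spatial distribution of
    zoonotic emerging-infectious-disease (EID) events on a coarse
    longitude-latitude grid. Disease-emergence events with uncertain
    geocoding (polygon footprints or 5 km point buffers) are contrasted
    against background samples weighted by a literature-derived reporting
    effort surface, using bootstrap ensembles of boosted regression trees
    with stagewise cross-validated tree selection. The package provides
    relative-influence and partial-dependence summaries with empirical
    confidence bands, AUC/TSS cross-validation under weighted and
    unweighted null samples, and the reporting-bias algebra that converts
    the fitted response into observed and bias-corrected risk-index maps.
    A synthetic-world generator with known true risk, biased detection and
    uncertainty footprints makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
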