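Package: sizedyn
Title: Bacterial Cell-Size Dynamics Along Population Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how bacterial cell volume changes along a
    population growth curve from population-level measurements alone.
    Converts per-cell segmentation measurements (projected area and length of
    sphero-cylindrical cells) into width, surface area and volume with
    outlier filtering; fits logistic or Gompertz biomass curves to OD600
    time series (with dilution handling) and extracts a time-varying growth
    rate; integrates a mean-field growth-division equation for the mean cell
    size; infers a time-varying division coefficient k(t) by fitting its
    double-sigmoid schedule to observed mean-size trajectories; estimates
    smoothed OD and CFU trends with confidence bands and propagates
    uncertainty into their ratio; and provides a stochastic single-cell
    simulator of exponential growth with size-proportional division hazard
    that acts as synthetic-data generator and oracle for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    mgcv,
    lhs,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
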