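Package: cortexwire
Title: Retrograde-Tracer Connectivity and Wiring-Cost Distances in Cortical Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification and analysis of mesoscale cortico-cortical
    connectivity from retrograde tracer injections registered to a labeled
    volumetric template. Computes per-injection and per-area connection
    strength (extrinsic fraction of labeled neurons, FLNe) and laminar origin
    (fraction of supragranular neurons, SLN) matrices; estimates interareal
    wiring distances as the lengths of simulated axonal tracts obtained by
    fast-marching geodesics through a gray/white-matter cost field;
    relates connectivity distance to the distance from primary sensory and
    motor areas with covariate-adjusted linear models; and compares local
    versus distant connectivity across functional networks with
    nonparametric tests. Includes a synthetic brain phantom generator so
    every stage can be exercised and validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
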