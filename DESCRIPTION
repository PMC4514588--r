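Package: soilcoda
Title: Compositional Analysis of Radiocesium Depth Profiles in Forest Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the vertical distribution of 137Cs (and other
    tracers) across the layers of forest-soil profiles as compositional data.
    Activities measured in depth-ordered horizons are closed to relative
    activities on the simplex and analysed with Aitchison-geometry methods:
    perturbation/powering arithmetic, centred and isometric log-ratio
    transforms, the variation matrix of pairwise log-ratio variances,
    exhaustive screening of two-group balances, fitting of linear processes
    (compositional lines) to layer pairs, hierarchical clustering on Aitchison
    distances, and classical versus minimum-covariance-determinant robust
    principal component analysis with outlier flagging. A seeded
    logistic-normal generator produces synthetic profile datasets with a
    configurable variation-matrix target, centre, and minority outlier
    cluster, so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ape,
    withr,
    optparse
Config/testthat/edition: 3
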