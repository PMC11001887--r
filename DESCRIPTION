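Package: folliclewave
Title: Vertex-Model Simulation and Quantification of Follicle-Cell Expansion Waves
Version: 0.1.0
Authors@R:
    person("Follicle", "Wave Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A modified cellular vertex model of the posterior-to-anterior
    expansion wave of the Drosophila follicular epithelium (ruffling,
    area-increasing and spreading phases under oocyte anterior-posterior
    growth), together with the quantification toolbox used to analyse it:
    cell-shape morphometrics (circularity, volume, flatten ratio), discrete
    boundary curvature and membrane-ruffle detection, rose diagrams,
    migration kinematics, autocorrelation period estimation, photobleaching
    correction, Gabor-bank fiber-orientation analysis, Van Steensel spatial
    cross-correlation and temporal lag-cascade estimation. Includes seeded
    synthetic-data generators so that every stage of the pipeline is
    testable without imaging data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
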