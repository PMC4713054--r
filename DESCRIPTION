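Package: PurkinjeFT
Title: Virtual-Population Simulation of Ventricular Activation with
    Purkinje Networks, False Tendons and Bundle Branch Block
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic biventricular anatomies from a statistical
    shape model (with papillary muscles and rule-based Streeter fiber
    orientation), grows endocardial Purkinje networks with a three-stage
    L-system, inserts false tendons with direct or delta terminations,
    models complete left bundle branch block, and computes myocardial
    activation maps by coupling an anisotropic Eikonal solver on
    tetrahedral meshes to the one-dimensional conduction network through
    delayed Purkinje-muscle junctions. Includes QRS-duration and
    ventricular-synchrony metrics and population-level experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
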