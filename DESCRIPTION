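Package: enzport
Title: Annotation of Enzyme Binding Pockets and Ligand-Transport Tunnels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for annotating biochemically relevant enzyme
    pockets and tunnels. Detects alpha-sphere binding pockets from protein
    structures and computes a 20-descriptor feature vector, selects the main
    pocket from the position of a bound (cognate) ligand by coverage rules,
    classifies pockets as buried, borderline or surface with a trainable
    predictor, finds ligand-access tunnels on the Voronoi graph of the
    heavy atoms with a probe-radius criterion, scores tunnel priority, and
    post-processes ligand-transport energy profiles (bound/surface/maximum
    energies, transport barriers, bottleneck-vicinity matching). Ships a
    synthetic-structure generator with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    RANN,
    nnet,
    e1071,
    class,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
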