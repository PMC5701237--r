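Package: rama
Title: Two-Stage Ensemble Prediction of Plant Ribosomal Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts plant ribosomal proteins from nine physicochemical
    attributes of amino acid sequences (residue-group proportions, mean
    hydropathy, mean residue mass, mean residue volume, and length). A first
    classifier ensemble separates ribosomal from non-ribosomal proteins and a
    second separates ribosomal proteins from histones; a sequence is called
    ribosomal only when its averaged ensemble probability passes a
    discriminant threshold in both stages. Includes information-gain
    attribute ranking with MDL-based supervised discretization, training-set
    assembly with 3:1 negative subsampling, inter-species, k-fold and
    jackknife evaluation with the Matthews correlation coefficient, and a
    seeded synthetic proteome generator so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    foreign,
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    nnet,
    rpart,
    caTools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
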