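Package: eduqgc
Title: Equivariant Quantum Graph Circuits for Molecular Property Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact statevector simulation of equivariantly-diagonalizable-unitary
    quantum graph circuits (EDU-QGC) for predicting scalar molecular properties
    such as the HOMO-LUMO gap from heavy-atom molecular graphs. Provides angle
    encodings of atom features (fixed schemes and a trainable angle-extraction
    network), permutation-invariant local and global readouts, parameter-shift
    gradients, an Adam training loop with periodic-validation model selection,
    matched classical message-passing baselines (gated graph network and graph
    convolutional layers), a valence-constrained synthetic molecule generator
    with a teacher-model labeller, and a command-line interface for reproducible
    generate/train/eval/inspect runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
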