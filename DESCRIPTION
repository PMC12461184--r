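Package: cgrnn
Title: Reaction Barrier Height Prediction with Condensed-Graph Message Passing Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts reaction barrier heights (activation energies, kcal/mol)
    from atom-mapped reaction SMILES using a directed message-passing neural
    network over the condensed graph of reaction (CGR). Atom features can be
    augmented with tabulated quantum-chemical descriptors and with 3D
    positional descriptors (atomic environment vectors, smooth-overlap power
    spectra) computed from reactant, transition-state and product conformers.
    Includes random, reaction-core-clustered and barrier-height-extreme
    dataset splitters, a reproducible training loop with AdamW and cosine
    annealing, permutation feature importance, and a synthetic fixture
    generator with a known graph-plus-geometry generative formula for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
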