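Package: lamevo
Title: Lamarckian and Darwinian Evolution of Modular Robots with Lifetime Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for studying Lamarckian versus Darwinian
    inheritance in evolving modular robots. Robot bodies are encoded as
    compositional pattern-producing networks (CPPNs) decoded breadth-first into
    module trees; brains are central pattern generator (CPG) networks whose
    weights live in a reversible, grid-indexed 440x14 genotype table; lifetime
    learning uses Reversible Differential Evolution (RevDE), and learned weights
    can be written back into the genome (Lamarckian mode) or discarded at
    reproduction (Darwinian mode). Includes a deterministic kinematic locomotion
    surrogate with a point-navigation fitness function, tree-edit-distance
    morphometrics (diversity, parent-child similarity, eight normalized body
    traits, learning delta), and an experiment harness with evaluation-budget
    bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
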