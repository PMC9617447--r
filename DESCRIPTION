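Package: igocsvm
Title: Binding-Mode Classification from Interaction Graphs with One-Class SVMs
Version: 0.1.0
Authors@R: person("LIT", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Encodes protein-ligand interactions detected in conformational
    ensembles (e.g. molecular dynamics frames of an agonist-receptor complex)
    as complete, distance-weighted interaction pseudo-atom graphs, compares
    graphs with a shortest-path graph kernel, and learns a one-class support
    vector machine definition of the reference binding mode with heuristic
    selection of the nu parameter (kneedle knee detection or median absolute
    deviation). Trained models classify docking poses, and hence molecules,
    as reference-like or not. Supporting machinery covers TRIPOS MOL2 input
    and output, geometric interaction detection, binding-site RMSD clustering
    with medoid selection of representative receptor conformations, an
    interaction-fingerprint Tanimoto baseline, screening metrics, and a
    synthetic binding-mode ensemble generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    cluster,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
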