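Package: stabgvp
Title: Protein Thermostability Change Classification with Geometric
    Vector Perceptron Graph Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies single- and multiple-point protein mutations as
    stabilizing or destabilizing from wild-type and mutant backbone
    structures. Builds rotation-equivariant residue graphs (scalar node
    features from six amino-acid encoder families, vector node features
    from backbone orientation, radial-basis edge distances and unit edge
    directions), trains a dual-graph geometric vector perceptron graph
    network with multi-head attention over the wild-type/mutant pair, and
    evaluates predictors symmetrically on direct and reverse mutations.
    Includes thermodynamic-cycle data augmentation (looping and
    reversibility), a mutation-type clustering train/test splitter with
    wild-type-level leakage control, and a synthetic fixture generator so
    the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
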