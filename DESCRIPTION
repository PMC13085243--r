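Package: psmilesRL
Title: Data-Free Reinforcement-Learning Inverse Design of Geometrical Isomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Generates substituents for a styrene scaffold in a compact
    SMILES-derived token grammar (P-SMILES) and trains a hierarchical
    five-policy agent with proximal policy optimization to maximize the
    isomerization energy gap between geometrical isomers. The chemical
    reward runs a multi-stage validity cascade (well-formedness, grammar
    decoding, heteroatom chain filter, valence sanity, closed-shell parity,
    3D embedding and identity round-trip) over a pluggable energy engine;
    a deterministic toy engine makes complete bounded chemical spaces
    enumerable for exact verification against a random-search baseline.
    Includes exact transfer-matrix censuses of bounded spaces, a
    Tanimoto-complement diversity reward, entropy-regularized PPO with
    top-K prioritized replay, and adapters for external tight-binding and
    conformer-sampling programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
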