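Package: causalmi
Title: Causal and Non-Causal Mixed Graphical Models from Multivariate
    Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based learning of mixed graphical models
    (undirected, directed and bidirected edges) from purely observational
    categorical data, allowing for unobserved latent variables. Edges are
    iteratively removed by collecting the most likely information
    contributors of each pair, with finite-size corrections based on
    BIC/MDL or decomposable normalized maximum likelihood (NML)
    complexities; retained edges receive permutation-based confidences and
    partial-correlation signs, and unshielded triples are oriented
    probabilistically from the sign of conditional 3-point information.
    Includes benchmark machinery: random Bayesian networks with
    multinomial conditional probability tables, hidden-variable masking, a
    d-separation oracle, Ising-like Monte Carlo samplers with
    effective-sample-size correction, and skeleton/endpoint scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
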