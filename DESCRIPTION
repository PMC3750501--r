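Package: specmap
Title: Mapping Behavioral Specifications to Parameter Regions of
    Biochemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse design of synthetic gene circuits. Behavioral
    specifications are expressed as differentiable functionals on the
    trajectories of a mass-action ordinary differential equation model.
    The map from kinetic design parameters to these behavioral features
    is linearized by forward sensitivity (variational) integration,
    inverted locally with a singular-value-decomposition pseudoinverse,
    and a specification region in feature space is covered with
    error-controlled feature balls whose preimages are parameter
    ellipsoids; every sampled parameter set inside an ellipsoid
    satisfies the specification up to a quantified reverse-forward
    error. Includes a five-state transcriptional sensor construct
    (auto-activating dimer with an external inhibitor input) as a
    built-in case study, a YAML configuration layer and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
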