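Package: argspace
Title: Spatial Inference on Ancestral Recombination Graphs under Brownian Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Likelihood-based spatial population genetics on ancestral
    recombination graphs (ARGs). Models the movement of genetic lineages as
    Brownian motion down the full ARG, conditioning on parental lineages
    meeting at recombination nodes, and computes maximum-likelihood estimates
    of dispersal rates and root locations together with the full Gaussian
    location distribution (mean, variance, confidence region) of every
    genetic ancestor. Includes tree-based and averaging-up baselines, an
    alternate midpoint-recombination model, exact joint-Gaussian reference
    computations for verification, a model-exact ARG/location simulator, and
    a scaled-down individual-based two-dimensional spatial simulator with
    full ARG recording.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), MASS, jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'arg-core.R'
    'path-matrix.R'
    'spatial-likelihood.R'
    'estimation.R'
    'ancestor-locations.R'
    'arg-io.R'
    'baselines.R'
    'oracle.R'
    'simulate-model.R'
    'simulate-ibd.R'
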