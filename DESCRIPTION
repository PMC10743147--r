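Package: BioSOSS
Title: Single-Object Scattering Sampling Simulations for
    Nanoparticle-Labeled Biomolecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates single-shot coherent X-ray scattering images of a
    biomolecule labeled with two gold nanoparticles, retrieves the
    three-dimensional inter-particle vector from each image by fitting the
    two-sphere interference model, and characterises retrieval accuracy
    across conformational ensembles and experimental parameter sweeps.
    Includes an Ewald-sphere detector model, Cromer-Mann atomic form
    factors, a homogeneous-sphere nanoparticle form factor, Poisson plus
    uniform detector noise, a synthetic fluctuating ssRNA conformer
    generator, nanoparticle label-site selection under steric constraints,
    and ensemble accuracy statistics with Gaussian fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    yaml,
    minpack.lm,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
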