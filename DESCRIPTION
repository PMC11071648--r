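Package: socotraj
Title: Developmental Trajectories of Social-Cognition Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference pipeline for lifespan trajectories of
    intrinsic functional connectivity (iFC) between meta-analytic
    social-cognition seed networks (empathy, theory of mind, moral cognition)
    and canonical cortical networks. Provides a synthetic cortical cohort
    generator (icosphere surfaces, contiguous parcellations, smooth seed
    maps, BOLD mixtures with planted age- and sex-dependent seed-to-network
    coupling), surface-domain BOLD preprocessing (volume discard, grand-mean
    scaling, Friston-24 and tissue nuisance regression, band-pass filtering,
    polynomial detrending), two-stage dual regression to subject-level
    network maps, vertex-wise age/sex general linear models with random
    field theory and Freedman-Lane permutation cluster correction, and
    normative percentile trajectory fitting via Gaussian location-scale and
    Box-Cox Cole-Green distributional regression with trajectory-shape
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    igraph,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'dualreg.R'
    'mesh.R'
    'group-inference.R'
    'ifc.R'
    'io.R'
    'methods.R'
    'nullmaps.R'
    'parcellation.R'
    'trajectory.R'
    'preprocess.R'
    'seedmaps.R'
    'simulate.R'
    'pipeline.R'
    'plots.R'
    'socotraj-package.R'
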