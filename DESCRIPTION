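Package: kinresponse
Title: Perturbation-Response Analysis of Random Kinetic Metabolic Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates thermodynamically consistent random kinetic models of
    metabolism (a minimal cofactor-coupled mass-action model, its catalytic
    variant, and the random catalytic reaction network toy model), integrates
    their stiff relaxation dynamics from randomized multiplicative
    perturbations, and quantifies responsiveness through the response
    coefficient chi (the peak log-space excursion relative to the initial
    displacement). Includes metabolite-clamping statistics (rho plus/minus),
    random network-expansion experiments, conserved-moiety analysis,
    multistability screening, elementary reaction decomposition, enzymatic
    rate-law templates, and a closed-form estimate of metabolite concentration
    fluctuations under gamma-distributed enzyme noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, deSolve, jsonlite, igraph
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'minimal_model.R'
    'model-methods.R'
    'dynamics.R'
    'response.R'
    'clamp.R'
    'expansion.R'
    'fluctuation.R'
    'rcrn.R'
    'io.R'
    'kinresponse-package.R'
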