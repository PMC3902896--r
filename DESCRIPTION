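Package: hrebind
Title: Thermodynamic Modeling of Steroid Receptor-DNA Binding Energetics and
    Transcriptional Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equilibrium models linking steroid receptor binding energetics at
    hormone response elements (HREs) to cellular transcriptional output.
    Fits Langmuir and dimer-assembly (total-affinity) binding models to
    quantitative footprint titration isotherms by global nonlinear least
    squares with bootstrap confidence intervals; globally rescales in vitro
    binding curves onto cellular fold-activation dose-response data via three
    shared scaling factors; provides affinity-function correlation diagnostics
    (cross-sections, linear and log-log regression, perturbation simulations);
    and simulates competitive assembly of multiple receptor species on
    multi-site promoters with a configurational partition function
    parameterized by dimerization, site-affinity and cooperativity constants.
    Includes seeded synthetic-data generators reproducing the statistical
    structure of footprint and reporter-assay data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
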