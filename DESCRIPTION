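Package: magnetogrowth
Title: Magnetic Gradient Forces on Intracellular Nanoparticle Chains and
    Bacterial Growth Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical magnetostatics of uniformly magnetized stripe
    magnets and antiparallel stripe pairs (reduced-unit field components,
    x-gradients, near-seam asymptotics), the piconewton-scale magnetic
    gradient forces they exert on chains of biogenic magnetic
    nanoparticles and on diamagnetic bacterial bodies, and the downstream
    growth-kinetics analysis: cell-cycle (B/C/D period) growth rates,
    log-linear fitting of exponential growth curves, doubling times,
    condition comparison, and a mitosis-shortening speed-up model for
    magnetosensitive Escherichia coli Nissle 1917. Includes a seeded
    synthetic growth-curve generator for the four culture conditions so
    the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'magnetostatics.R'
    'magnetoforces.R'
    'growth.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
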