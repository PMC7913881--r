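Package: hcdkin
Title: Steady-State Kinetics of the HcdE 7-Hydroxycoumarin Reductase
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the NADPH-dependent reduction of
    7-hydroxycoumarin by the HcdE alcohol-dehydrogenase-type ene-reductase
    from Pseudomonas mandelii 7HK4. Implements the ping-pong bi-substrate
    rate law with pseudo-competitive substrate inhibition, a mass-action
    ODE simulator of the underlying mechanism used as an independent
    oracle, spectrophotometric assay conversions (Beer-Lambert, initial
    rates, relative substrate activities), weighted nonlinear
    least-squares parameter estimation with profile-likelihood and
    bootstrap diagnostics, RT-qPCR relative quantification against a 16S
    reference, a pathway compound registry with adduct m/z computation,
    and seeded synthetic-data generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
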