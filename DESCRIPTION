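Package: citflux
Title: Compartmentalized 13C Metabolic Flux Analysis of Citrate Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for stationary 13C metabolic flux analysis (MFA) of
    compartmentalized central carbon metabolism, built around extracellular
    citrate catabolism in hepatoma cells. Provides an atom-transition network
    model with separate mitochondrial and cytosolic pools, elementary
    metabolite unit (EMU) simulation of steady-state mass isotopomer
    distributions under multi-tracer designs ([U-13C6]glucose,
    [U-13C5]glutamine, [2,4-13C2]citrate), natural-abundance correction of
    GC-MS fragment distributions, mole percent enrichment and M1/M2
    diagnostics, variance-weighted least-squares flux fitting with
    profile-likelihood confidence intervals, isotopomer spectral analysis
    (ISA) of de novo lipogenesis, extracellular uptake and secretion flux
    estimation under exponential growth, and seeded synthetic-data generators
    for end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    pracma,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
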