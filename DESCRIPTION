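Package: invscape
Title: Single-Cell Invasion Landscapes from Expression Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers single-cell invasion landscapes w(z) -- the probability
    that a cell at log10 expression level z crosses a Boyden-chamber membrane
    during one invasion assay -- from seeded and invaded flow-cytometry
    distributions together with population invasiveness, via the Bernoulli
    thinning identity or a dose-sweep constrained least-squares fit. Provides
    exact Ornstein-Uhlenbeck simulation of fluctuating log10 expression,
    Monte Carlo invasion assays on a landscape, Price-equation predictions of
    selection-induced shifts in trait mean and variance with selection-mode
    classification, mechanistic response models (hemin-accelerated protein
    degradation, incoherent feedforward loops), transwell and proliferation
    assay arithmetic, and a calibrated synthetic single-cell data generator
    for benchmarking landscape recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
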