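Package: hwpopsim
Title: Forward-Time Simulation of One-Locus Diploid Populations and
    Diagnostics of Hardy-Weinberg Equilibrium
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward-time, couple-based simulation of a one-locus/two-allele
    diploid population with random or fixed-probability (non-random) mating,
    bounded carrying capacity with random culling, and scheduled population
    bottlenecks. Provides the Hardy-Weinberg chi-square goodness-of-fit
    machinery on whole populations and subsamples, ensemble analysis of the
    chi-square distribution over replicate populations (false-negative and
    false-positive rates of the Hardy-Weinberg test, exponential tail fits,
    two-sample comparison), and allele-frequency autocorrelation analysis
    that discriminates neutral drift from stable (mean-reverting) dynamics
    via exponential decay fits and relaxation times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: PopulationGenetics, Genetics, StatisticalMethod, TimeCourse
RoxygenNote: 7.3.3
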