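Package: clockloops
Title: Robustness and Entrainment of Competing Circadian Feedback Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcriptional-translational feedback
    architectures of circadian clocks. Implements four ordinary-differential-
    equation models (single, semi-dual, dual and redundant feedback), a
    two-phase parameter search (random sampling seeding a genetic algorithm)
    that harvests kinetic parameter sets producing target circadian
    oscillations, quasi-multiparameter sensitivity (QMPS) as a fast measure
    of robustness to uncertainty in all kinetic parameters, kinetic-symmetry
    constrained search spaces, the loop-balance statistic gamma, and
    entrainment-probability maps under square-wave light-dark forcing of the
    clock-protein degradation rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
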