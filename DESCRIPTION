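Package: uterosim
Title: Cellular-Automaton Simulation of Organ-Level Uterine Contractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how regional contractions of the pregnant human uterus
    synchronize into organ-level contractions of labor through pressure-tension
    mechanotransduction. The uterine wall is divided into functional regions
    (the patches one propagating action-potential burst can recruit); each
    region is a cell of a three-rule cellular automaton in which intrauterine
    pressure is the mean of regional contractile activities, pressure sets
    regional passive tension through a per-region Law-of-Laplace anatomy
    factor, and tension above a per-region threshold triggers a bounded
    action-potential burst followed by a refractory period. Regional
    heterogeneity is drawn from seeded three-parameter Weibull distributions.
    Includes trace analysis (contraction detection, pseudo-Montevideo units,
    per-contraction pacemaker identification, behavior classification),
    uterine-geometry arithmetic, named scenario sweeps (tocolytic/uterotonic
    dose series, region-count sweeps, paired tissue-strip experiments), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
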