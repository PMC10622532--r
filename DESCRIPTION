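Package: icualloc
Title: Two-Stage Multi-Objective ICU Bed Allocation Under Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans intensive-care-unit bed allocation over a short horizon for
    three patient populations (current ICU patients, scheduled elective
    admissions, and Poisson-distributed emergency arrivals) and repairs the
    plan when lengths of stay extend. A first stage balances bed occupancy,
    elective delay (weighted by loss of chance if postponed) and the emergency
    admission rate with a problem-specific NSGA-II; a second stage re-allocates
    beds under length-of-stay extensions, maximizing similarity to the original
    plan while minimizing added beds, via three repair strategies including a
    constrained re-run of the evolutionary search. Multi-objective simulated
    annealing and tabu search baselines, a seeded synthetic-instance
    generator, scenario sweeps over extension distributions, and occupancy
    probability reporting are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
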