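Package: strokecea
Title: Decision-Tree and Markov Cohort Cost-Effectiveness Model for
    Neuroprotection in Acute Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid decision-tree / Markov cohort model comparing two
    neuroprotective strategies for acute ischemic stroke from a healthcare
    system perspective.  Day-90 modified Rankin Scale outcomes feed a
    long-term annual-cycle state-transition model with recurrent-stroke
    tunnel states, background mortality adjusted by disability-specific
    hazard ratios, half-cycle correction and discounting.  Produces
    incremental cost-effectiveness ratios and net monetary benefit at
    several horizons, one-way (tornado) sensitivity analyses, and
    probabilistic sensitivity analysis with Dirichlet, beta, gamma and
    lognormal parameter distributions, cost-effectiveness plane output and
    acceptability curves.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
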