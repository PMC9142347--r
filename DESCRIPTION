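Package: metstab
Title: Multi-Environment Trial Analysis and Stability for Participatory
    Wheat Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical analysis of multi-environment plant breeding
    trials: spatially corrected genotype BLUEs from randomized complete
    block and augmented designs, REML variance decomposition for crossed
    genotype-by-location-by-year random effects, broad-sense heritability
    on an entry-mean basis with harmonic-mean divisors, Finlay-Wilkinson
    joint regression and Wricke's ecovalence stability statistics, GGE
    biplots with which-won-where mega-environment grouping, Dunnett
    many-to-one comparison against a check cultivar, Fusarium head blight
    incidence/severity/index scoring, percentile-based selection filters,
    and mixed models for evaluator (baker and taster) score panels. A
    synthetic trial-data generator with known truth supports parameter
    recovery studies and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    emmeans,
    mvtnorm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
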