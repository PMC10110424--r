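Package: orgcycle
Title: Cell-Cycle Kinetics, Morphometry and Variability Statistics for
    Brain Organoid Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates cell-cycle phase durations (G1, S, G2M and total
    cycle length) in asynchronously cycling neural progenitor populations
    from sequential IdU/BrdU pulse labelling combined with flow-cytometric
    DNA-content phase counts. Includes a mechanistic simulator of cycling
    progenitor populations with virtual dual-pulse labelling, synthesis and
    gating of flow-cytometry-like event tables, per-organoid morphometry
    (batch-normalised projected area, relative neural-rosette area, marker
    areal density, relative mean fluorescence intensity), a statistical
    battery for genotype effects on means and variances (Welch's ANOVA,
    Games-Howell, Levene and variance-ratio tests, Cliff's delta,
    omega-squared, batch-aware mixed-effects contrasts, delta-delta-Ct
    qPCR quantification), and a study-design generator for multi-batch,
    multi-line organoid experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    graphics,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
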