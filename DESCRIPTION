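Package: prc2suite
Title: Proliferation-Adjusted Prognosis, H3K27me3 Homeostasis Kinetics, and
    Polycomb Target Classification
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the interplay between cell proliferation and
    Polycomb repressive complex 2 (PRC2) activity. Provides a survival-analysis
    suite (Kaplan-Meier, log-rank, univariate Cox with Efron ties,
    Benjamini-Hochberg FDR) built around proliferation-metagene adjustment of a
    marker transcript in tumor cohorts; a kinetic model of H3K27me3 abundance
    under enzyme-dependent deposition and cell-division dilution; classification
    of PRC2 target genes from promoter mark density and expression time courses
    with a rank-product differential test; single-cell analysis of deterministic
    versus stochastic derepression; and seeded synthetic-data generators that
    emulate the statistical structure of every input so all stages are testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
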