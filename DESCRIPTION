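Package: iircross
Title: Dynamic Cross-Talk Model of the Epithelial Innate Immune Response to dsRNA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of an integrated mass-action model of the
    epithelial innate immune response to double-stranded RNA, in which the
    RIG-I/MAVS -> IRF3 and TLR3 -> NF-kB signaling arms are coupled by mutual
    transcriptional repression and by the TNFAIP3/A20 and IkBa negative
    feedback loops. Provides deterministic (ODE), exact stochastic (Gillespie)
    and hybrid (stochastic gene states over a deterministic bulk) simulation of
    the 83-species / 150-reaction network; dsRNA dosimetry; in-silico siRNA
    knockdown and knockout experiments; lognormal-dose cell ensembles;
    single-cell nucleus/cytoplasm ratio analysis with cubic detrending and
    Fourier periodograms; a relative-error fit score with per-series scaling
    and staged coefficient refinement; and a synthetic-data generator that
    emulates triplicate Q-RT-PCR/SRM-style measurement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
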