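Package: nomefoot
Title: Nucleosome Footprinting Analysis for NOMe-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing nucleosome occupancy and methylome sequencing
    (NOMe-seq) experiments, in which the M.CviPI GpC methyltransferase labels
    accessible chromatin so that a single bisulfite library reports both
    endogenous CpG (HCG) methylation and exogenous GpC (GCH) accessibility.
    The package fits a two-state beta-binomial hidden Markov model to the
    ordered GCH methylation series of a sample, decodes methyltransferase
    accessible and protected regions (MARs/MPRs) by the Viterbi algorithm,
    calls nucleosome-depleted regions (NDRs) against a local protected
    background with an exact one-tailed binomial test and Benjamini-Hochberg
    FDR control, and intersects biological replicates. Around the model it
    provides promoter methylation classification (UU/MU/MM), a positional
    Pearson autocorrelation statistic for nucleosome phasing, anchor-aligned
    profile matrices with hierarchical clustering, z-score normalisation of
    binned signal tracks, megabase-scale accessibility domain summaries, and
    a calibrated synthetic NOMe-seq generator so that every stage can be
    exercised end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
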