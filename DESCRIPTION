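Package: palmflow
Title: Landscape Genetics of Palm Gene Flow: Kinship, Parentage and
    Forest-Cover Inference
Version: 0.1.0
Authors@R:
    person("palmflow", "developers", email = "palmflow@example.org",
           role = c("aut", "cre"))
Description: Tools for landscape-scale analyses of gene flow in plant
    populations genotyped at codominant microsatellite (SSR) loci.
    Implements pairwise Loiselle kinship coefficients and distance-class
    spatial genetic structure (SGS) profiles with permutation envelopes,
    single-parent (unknown sex) parentage assignment by LOD score and the
    Delta statistic with simulation-derived critical values, Mendelian
    exclusion counts, per-locus paternity indices with combined index and
    paternity probability, binomial GLMs and linear mixed models relating
    assignment outcomes and gene-flow distances to landscape forest cover,
    and Monte Carlo randomization tests of GLM deviance and regression R
    squared. A synthetic-data generator with Mendelian inheritance,
    genotyping error and a cover-dependent dispersal kernel provides
    ground-truthed datasets for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
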