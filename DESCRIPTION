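Package: pleiomap
Title: Pleiotropy Testing and Phenotype Maps from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Plei", "Omap", email = "maintainer@pleiomap.org", role = c("aut", "cre"))
Description: Investigates pleiotropic architecture across phenotypes using only
    genome-wide association study (GWAS) summary statistics. For every pair of
    phenotypes, a four-group Beta-Uniform mixture model is fitted to the two
    p-value vectors by expectation-maximization, and a likelihood-ratio test
    of independent signals yields a pleiotropy p-value. The resulting matrix
    of pairwise p-values is turned into a two-dimensional phenotype map via a
    Box-Cox distance transformation followed by isomap (epsilon-neighborhood
    graph, shortest-path geodesics, classical multidimensional scaling), with
    optional k-means or hierarchical clustering of the embedded coordinates.
    Joint association mapping reports, for a chosen phenotype pair, the SNPs
    shared between the two traits at a user global false discovery rate based
    on local FDR values. A simulator generating summary statistics with known
    latent association structure makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
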