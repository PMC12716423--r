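Package: alpassembly
Title: Joint Range-Biome Diversification Models and Arctic-Alpine Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how regional alpine floras are assembled.
    Implements a compound-state cladogenetic state-dependent
    speciation-extinction (ClaSSE) model in which a lineage's state couples a
    geographic range (an adjacency-constrained set of regions) with occupancy
    of the alpine versus nonalpine biome; provides exact likelihood
    computation, forward simulation, and stochastic character mapping with
    hidden (unobserved) speciation events. Mapped histories are stored in a
    structured JSON event format and classified into assembly processes (in
    situ speciation, subset speciation, colonization, niche expansion, niche
    contraction, local extinction), from which binned per-capita rate series
    with quantile envelopes, biotic-interchange matrices, and
    assembly-proportion summaries are derived. A companion module builds
    arctic-alpine habitat networks from gridded temperature fields (alpine
    classification, resistance surfaces, least-cost paths between patches) and
    computes the probability-of-connectivity statistic through time.
    Synthetic-data generators produce paleo-temperature grid sequences,
    simulated clades under known rates, and occurrence tables for the biome
    classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
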