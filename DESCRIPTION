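Package: cloneBow
Title: Multicolor (Brainbow-Style) Clonal Analysis of Neural Progenitor Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multicolor (Brainbow/zebrabow) clonal analysis of neural
    progenitor populations: normalization of measured RGB fluorescence onto the
    ternary simplex and classification into 25 color identities, clone calling by
    shared color identity and spatial contact, traceability filtering and linking
    of clones across timepoints, lineage statistics (progenitor/neuron fate calls,
    PP/PN/NN division-mode classification from tracks or from endpoint clone
    composition, sister-cell concordance and division synchrony, clonal growth,
    division-mode time-courses), and the group-comparison statistics used in
    developmental clonal studies (normality-gated Welch or Mann-Whitney tests and
    one-way ANOVA with Dunnett contrasts). A stochastic generator of synthetic
    multicolor clonal datasets with full ground truth (recombination outcomes,
    lineage trees, division modes, fates, spatial layout, channel noise) makes
    every stage of the pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    xml2,
    jsonlite,
    multcomp,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
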