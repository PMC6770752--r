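Package: coexmod
Title: Gene Co-Expression Module Mining and Differential Module Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines possibly-overlapping gene co-expression modules from
    bulk expression matrices with the local maximum Quasi-Clique Merger
    (lmQCM) algorithm, summarises each module by its first principal
    component, and tests modules for differential expression between
    sample groups with a permutational ANOVA on inter-sample distances.
    Includes probe-to-gene collapsing and variance filtering for
    microarray matrices, module overlap (Venn) decomposition, Fisher
    exact over-representation against GMT gene-set collections with
    Benjamini-Hochberg control, gene-level copy-number calls from
    segmented (SEG) data, and a latent-factor synthetic-data generator
    that plants correlated gene blocks, group shifts, probe multiplicity
    and copy-number events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
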