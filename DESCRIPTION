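Package: coremic
Title: Core Microbiome Identification from Presence/Absence Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the core microbiome of a habitat of interest by
    meta-analysis of taxonomy-labelled OTU tables from heterogeneous
    studies. Tables are collapsed to unique taxonomy, merged on shared
    taxa, binarized to presence/absence, and each taxon is tested for
    enrichment of presence in an interest group versus an out-group with a
    one-tailed Fisher's exact test; false discovery rate is controlled by
    Benjamini-Hochberg and taxa passing q-value and presence-percentage
    criteria are reported, with a taxonomy-tree rendering of the result.
    Includes readers for BIOM v1 (JSON) and tab-delimited tables, a seeded
    synthetic community generator with planted core taxa for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    biomformat,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    ape,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
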