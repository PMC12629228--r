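Package: sigconnect
Title: Connectivity Analysis of Transcriptomic Signatures with a Consensus Meta-Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores a query gene-expression signature (gene-level z-scores)
    against a repository of reference perturbation signatures using six
    connectivity methods: Pearson, Spearman and cosine similarity over the
    whole gene list, and three extreme-gene methods (weighted connectivity
    score, signed-rank connection strength score, and eXtreme Sum).
    Precomputed permutation backgrounds give empirical p-values for the
    extreme-gene statistics, and a 0-6 meta-score counts how many methods
    place a query-reference pair within the top 5% of a screen. Includes
    positive (mimic) and negative (reversal) screening pipelines, GCT/TSV/JSON
    readers and writers, a synthetic-repository simulator with planted
    signals, radar/GSEA/Venn plot data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    graphics,
    grDevices,
    jsonlite,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
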