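Package: phosflow
Title: Differential Phospho-Signaling Analysis for Isobaric-Label
    Phosphoproteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed (isobaric-label)
    phosphoproteomics of acute versus chronic receptor stimulation:
    signal-to-noise to relative-abundance normalization, phosphosite
    localization filtering, phosphosite-to-protein normalization, log2
    fold-change contrasts between stimulation regimes, tiered merging of
    measured phosphosites with phosphorylation-site and kinase-substrate
    reference databases, Kolmogorov-Smirnov significance scans over
    functional and kinase-substrate groups, hypergeometric
    over-representation of outlier proteins, CellDesigner-flavored SBML
    signaling-map audits, and kinase-substrate network export in
    Cytoscape-compatible formats.  A synthetic-data generator with
    planted group-level effects and a ground-truth record makes every
    stage testable without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
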