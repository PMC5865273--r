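Package: taxocover
Title: Unbiased Taxonomic Annotation of Metagenomic Reads by Indicator
    Scoring and Set Cover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies metagenomic reads against a reference taxonomy by
    scoring candidate nodes of the LCA skeleton with classification-error
    indicators (Rand index, F-measure, Jaccard coefficient, area under the
    ROC curve, Youden J, Yule/Matthews phi), resolves sample-wide annotation
    ambiguity by reducing it to a minimum-total-size set cover problem
    (greedy and exact branch-and-bound solvers), and derives relative
    abundance profiles with rank roll-up. Includes readers for Newick, NCBI
    taxonomy dump and Greengenes lineage formats, a BLAST tabular ingestion
    step with top E-value tie filtering, and an enumeration benchmark that
    compares the indicators exhaustively on generated tree topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
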