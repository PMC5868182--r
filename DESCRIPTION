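Package: studysim
Title: Study-Wise Annotation Models and Ontology-Based Semantic Similarity
Version: 0.1.0
Authors@R:
    person("Maintainer", "Anonymous", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents ontology annotations of diseases or genes not as flat
    class lists but grouped by the study (publication, paragraph) each
    annotation was derived from, and implements semantic similarity measures
    that exploit this structure: Resnik best-match-average over most
    informative common ancestors, cosine and Jaccard similarity on
    ancestor-propagated profile vectors, and a study-wise meta-measure that
    matches each query study against the best-fitting item study. Includes an
    OBO parser restricted to is_a edges, information-content computation, a
    deterministic longest-match dictionary concept recognizer for sectioned
    full-text disease descriptions, a group-recovery benchmark (ranks,
    precision-recall curves, Wilcoxon signed-rank comparisons) and a
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
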