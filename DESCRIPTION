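Package: goeffects
Title: Hypothesis-Driven Signed Effect Analysis of Expression Data with the Gene Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests user-chosen biological hypotheses against differential
    gene-expression datasets using the Gene Ontology (GO). Gene annotations
    are matched to hypothesis GO terms by true-path-rule traversal of the
    ontology DAG, term names are parsed for positive/negative effect cues,
    conflicting signs are resolved by a user policy, and per-gene qualitative
    effects are combined with expression values into quantitative pro, anti
    and net effect summaries per hypothesis, with tabular (TSV) and graphical
    (SVG) output. Includes an OBO ontology parser, a GAF 2.x annotation
    reader, a Porter-stemmer based hypothesis-term search over the ontology,
    deterministic synthetic fixture generators, and a packaged nine-cytokine
    qualitative-effect study matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
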