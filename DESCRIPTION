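Package: trunkSEP
Title: SEP Partonomy Modelling and EL Classification of Trunk Regional Anatomy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Formal-semantic machinery for regional anatomy in the OWL 2 EL
    fragment. Provides the Structure-Entire-Part (SEP) meronymic modelling
    pattern, Body-Wall-Cavity-Contents aggregation patterns, a completion-rule
    EL classifier with role hierarchies and role chains, classification
    impact diffing for ontology quality assurance, readers and writers for a
    simplified tab-delimited RF2 dialect and an OWL functional-syntax subset,
    a seeded random ontology generator with an independent naive entailment
    oracle, and a complete executable partonomy of the human trunk (thorax,
    abdomen, pelvis) including the clinical-region variants of "abdomen".
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
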