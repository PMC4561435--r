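Package: radtex
Title: Ontology-Driven Information Extraction from Knee MRI Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based, ontology-driven information extraction pipeline for
    narrative knee MRI reports. Given an OBO ontology and plain-text reports,
    the package recognises ontology concepts with soft dictionary matching
    (TF-IDF weighted Jaro-Winkler similarity), resolves coordination,
    enumeration, negation, hyponym coreference and polysemy, segments
    sentences into clause-level units, and fills finding/anatomy templates
    that are emitted as JSON. It also ships an evaluation suite (per-slot and
    per-record micro-averaged precision/recall/F, chance-corrected agreement,
    concept-ablation experiments) and a synthetic report generator with
    generation-time gold annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
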