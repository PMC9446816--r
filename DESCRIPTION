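Package: relexr
Title: Biomedical Semantic Relation Classification with Masked-Entity Inputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for sentence-level biomedical relation classification
    under an eight-type semantic relation schema with a three-level
    cause/increase/decrease hierarchy. Provides readers and writers for
    annotated corpora (TextAE-dialect JSON and a canonical tab-separated
    relation table), five fine-tuning input-construction strategies
    (default, entity markers, masked entities, two masked sentences, and
    two-sentence entity tokens), three classification heads (CLS token,
    two-token, three-token), a seeded tiny transformer encoder with an
    AdamW training harness and stratified k-fold cross-validation,
    per-class precision/recall/F1 evaluation reports, and a synthetic
    corpus generator whose cue grammar (verb polarity, negation modifiers,
    quantity phrases) mirrors the annotation scheme.
License: MIT + file LICENSE
Encoding: UTF-8
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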