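Package: ptrex
Title: Few-Shot Temporal Relation Extraction Between Phenotypes and Time
    Expressions in French Clinical Reports
Version: 0.1.0
Authors@R:
    person("Clinical NLP", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to extract temporal relations between pre-annotated
    phenotype mentions and time expressions in French (pediatric) clinical
    reports with few-shot prompted large language models. Reads and writes
    the BRAT standoff annotation dialect, formalizes the seven-relation
    schema (BEGINS-AT, ENDS-AT, CONTAINS, OVERLAP, BEFORE, BEFORE-OVERLAP,
    SIMULTANEOUS) as an interval-semantics labeling function, generates
    seeded synthetic annotated corpora with a latent patient timeline,
    assembles multi-class, binary and zero-shot prompts from a curated
    example bank, talks to any locally served chat-completion endpoint (or a
    deterministic mock), resolves conflicting binary predictions by training
    sample rarity, and scores predictions per relation type including
    pairwise inter-annotator agreement as average F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    httr,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
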