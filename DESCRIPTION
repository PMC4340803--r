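Package: medmod
Title: Hospital Process Modeling and Slice-Based Process Querying
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An executable engine for a domain-specific hospital process
    modeling language (MedMod) and its companion process query language
    (PQL). Process models are built from activities with typed attributes
    and four relation kinds (follows, composition, interruption, extension);
    runtime data are activity instances grouped into disjoint slices, one
    per master-activity transaction. The package validates models and traces,
    generates synthetic conformant traces by stochastic simulation, and
    answers ad-hoc queries (comparison filters, per-slice aggregate filters,
    top/bottom-k partitioning, time intervals, grouping, and Count/Sum/Average
    retrieval) with instrumented linear-time evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
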