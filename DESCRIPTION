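Package: coralkey
Title: Polytomous Identification Keys, with the Genus-Level Key to
    Azooxanthellate Scleractinia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A general engine for polytomous (dichotomous and
    polychotomous) taxonomic identification keys: a typed decision-graph
    data model with a JSON document format, structural validation,
    stepwise and scripted identification sessions, exhaustive path
    enumeration, a derived multi-access (polyclave) character matrix with
    order-free filtering, DOT and CSV exports, and a seeded random key
    generator with structural defect injection for property testing.
    Ships, fully encoded, a comprehensive published key to the 120 genera
    and 7 additional subgenera of the Recent azooxanthellate Scleractinia
    (stony corals), together with its bibliography of previously
    published species-level keys and the controlled vocabulary of
    geographic range abbreviations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
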