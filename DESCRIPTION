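Package: deldesign
Title: Combinatorial Design and Diversity Analysis of DNA-Encoded Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to design DNA-encoded chemical libraries (DELs) from a
    functional-group ontology, a set of DNA-compatible reactions and
    building-block collections. Exhaustively generates feasible multi-cycle
    designs, merges experimentally combinable designs into library designs,
    estimates product heavy-atom distributions by histogram convolution to
    maximize library size under a median molecular-size constraint without
    enumeration, draws seeded random product samples by virtual synthesis,
    and prioritizes libraries by Tanimoto path-fingerprint diversity against
    reference collections using a greedy spread design. Ships a synthetic
    building-block and reference-collection generator so the whole pipeline
    is testable without proprietary catalogs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Open Babel 3 command-line tools (obabel); Python 3 with
    RDKit for structure enumeration.
Config/testthat/edition: 3
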