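Package: BglBrickKit
Title: Design and Characterization Toolkit for BglBrick Expression Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico cloning CAD engine for the BglBrick (BBF RFC 21)
    expression-vector platform. Models DNA sequences with circular topology,
    restriction-site scanning, digestion into end-typed fragments and
    cohesive/blunt ligation; validates and idempotently assembles BglBrick
    parts; proposes codon-usage-aware single-nucleotide substitutions to
    remove forbidden restriction sites; designs tailed, mutagenic and
    SOE-fusion PCR primers; generates the combinatorial pBb vector library
    with its three-module architecture and nomenclature; and computes
    quantitative datasheet panels (specific fluorescence, inducer dose
    response, inducer crosstalk, catabolite repression, and qPCR
    standard-curve plasmid copy number), with seeded synthetic-data
    generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
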