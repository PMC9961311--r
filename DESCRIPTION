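Package: intrax
Title: Integrated-Similarity Read-Across for Analogue Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies source-chemical analogues for read-across by combining
    three independent similarity views: structural similarity (Tanimoto over
    881-bit PubChem-style substructure fingerprints), mechanistic similarity
    (shared structural alerts for human aromatase toxicity, matched as SMARTS),
    and metabolic similarity (Tanimoto over 5-bit cytochrome P450
    isoform-inhibition profiles). The intersection of the three candidate
    lists forms the analogue category and a majority vote over the category
    predicts qualitative activity. Includes dataset curation helpers (salt
    stripping, tautomer-collapsing structure keys, potency conversion,
    duplicate reconciliation, azole classification), leave-one-out validation
    with confusion-matrix statistics, case-study fixtures, a synthetic
    homologous-series generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    caret,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
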