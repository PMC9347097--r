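Package: msadta
Title: Multi-Scaled Self-Attention Models for Drug-Target Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequence-based drug-target binding affinity regression.
    Trains byte-pair-encoding (BPE) subword vocabularies on SMILES and protein
    sequence corpora, encodes sequences as padded integer vectors, and fits a
    multi-scaled self-attention regressor in which each attention head is
    restricted to a diagonal band of configurable half-width. Includes the
    evaluation statistics standard in this field (mean squared error,
    concordance index, the r^2_m external-validation metric and the Kd to pKd
    transform), readers and writers for benchmark affinity datasets, seeded
    synthetic data generators for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
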