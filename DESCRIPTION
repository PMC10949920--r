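Package: riconf
Title: Evidence Architecture and Confidence Calculus for Transcription
    Factor Regulatory Interactions
Version: 0.1.0
Authors@R:
    person("Riconf", "Developers", email = "riconf@example.org",
           role = c("aut", "cre"))
Description: Tools for working with the evidence architecture behind
    curated transcription-factor regulatory interactions (RIs) in
    bacterial regulatory-network databases. Provides a declarative
    evidence-type catalog with independence groups, the additive-evidence
    confidence calculus that assigns weak, strong or confirmed levels to
    each interaction, mapping of high-throughput TF-binding peaks
    (ChIP-seq, ChIP-exo, gSELEX, DAP-seq) onto regulatory sites to enrich
    their evidence, recovery benchmarking of HT methods against
    classically supported sites with nonparametric method comparison,
    flexible gold-standard extraction with method exclusion, and a
    synthetic-corpus generator with planted ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
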