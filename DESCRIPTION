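Package: causalMA
Title: Model Averaging over Confounder Adjustment Sets from Causal Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates sufficient and minimally sufficient confounder
    adjustment sets from a user-supplied directed acyclic graph via the
    backdoor criterion, fits one risk-ratio regression (log-binomial with a
    modified-Poisson fallback) per adjustment set on that model's complete
    cases, and combines the per-set exposure estimates by three averaging
    schemes: Akaike-weight information-criterion averaging with the
    unconditional standard error, inverse-variance weighting with a
    sample-size-weighted pooled standard error, and bootstrap pooling of the
    replicate-by-model estimate distribution. Reports averaged risk ratios,
    confidence intervals, and confidence-limit ratios, and includes a
    structural cohort simulator with known causal effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    sandwich,
    stats,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
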