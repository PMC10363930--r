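Package: relassure
Title: Probability of Success for Related Combination Therapy Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian assurance (probability of study success) for a planned
    clinical trial of a combination therapy, borrowing strength from the
    observed outcome of a related combination through a multivariate normal
    prior on the treatment effects. Trial outcomes enter as score statistics
    with Fisher information; conjugate updating yields the joint posterior,
    whose margins feed a closed-form or Monte-Carlo assurance calculation.
    A robust two-component mixture (uncorrelated/correlated) with data-driven
    weights based on truncated-posterior overlap protects against borrowing
    from an unrelated study. Includes a replication engine for go/no-go
    operating characteristics and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
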