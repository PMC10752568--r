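Package: seqlearn
Title: Learning Costs and Benefits of Sequence Representation in Associative Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when representing stimulus sequences pays off for a
    learning organism. Provides a closed-form cost-benefit model of decision depth
    (the number of most-recent stimuli a decision rule can access), including
    lifetime-utility curves and optimal-depth scans over alphabet size and lifespan,
    and an agent-based go/no-go simulator in which associative learners equipped
    with trace-decay, fixed-depth, or flexible subsequence memory representations
    are trained by error-correction learning in synthetic template-sequence
    environments. Includes generators for worlds that vary the temporal
    distribution of information and the fraction of information carried by
    stimulus order, a fast compiled simulation engine with a pure-R reference
    implementation, frozen-test-set performance curves over replicates, and
    plotting and summary utilities for comparing representation strategies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
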