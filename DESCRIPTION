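Package: crosscoder
Title: Direction of Cross-Disease Transcriptomic Association from Paired
    Autoencoder Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the direction (positive, inverse, indeterminate) of the
    transcriptomic association between two diseases from case/control
    expression cohorts.  Shared differentially expressed genes are identified
    with empirical-Bayes moderated t-tests after parametric empirical-Bayes
    batch adjustment; a one-node-bottleneck autoencoder is trained per
    disease to summarise each sample's expression over the shared genes as a
    single "pseudogene" score; held-out cases are projected through both
    encoders and the Spearman correlation of the paired scores gives the
    association direction.  Includes a synthetic cohort generator with a
    planted latent severity factor of known association sign,
    over-representation analysis against user-supplied gene sets, and
    degree-based hub-gene ranking on confidence-filtered interaction
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    withr
Config/testthat/edition: 3
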