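Package: eeanet
Title: Multiphasic Extracellular Enzyme Kinetics and Time-Delayed
    Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving high-affinity and low-affinity extracellular
    enzymatic systems from substrate-ladder hydrolysis assays, and for linking
    the resulting kinetic parameters to plankton and bacterial community time
    series. Fits four nested kinetic models (first-order, Michaelis-Menten,
    and their two-isoenzyme combinations) to response curves by multi-start
    nonlinear least squares, selects among them by the small-sample corrected
    Akaike information criterion, and derives cell-specific maximum hydrolysis
    rates. Provides delay-limited local similarity analysis with permutation
    significance and Benjamini-Hochberg correction, assembly of signed,
    possibly time-lagged association networks with Cytoscape-compatible
    export, plate-reader assay processing, and a synthetic-data generator for
    both response curves and seasonal multivariate campaigns with planted
    couplings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
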