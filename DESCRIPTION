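Package: beem
Title: Biclustering-Based Extraction of Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene set-based discovery of expression modules in genes-by-samples
    expression matrices. Each input gene set is screened with the BEEM
    statistic: a maximal coherent core of the set seeds the Iterative
    Signature Algorithm (ISA), and the overlap between the input set and the
    resulting biclustered gene set is calibrated through a three-step p-value
    procedure (hypergeometric screen, empirical null, regression
    extrapolation) over a grid of ISA threshold settings. Includes two
    comparator screens (coherence-based EEM and single-sample analysis with
    Fisher/Brown combined p-values), simulation models with labelled gene-set
    libraries for AUC benchmarking, and post-hoc module analyses (activity
    profiles, module-overlap tests, annotation enrichment, and
    Kullback-Leibler clustering of position weight matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
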