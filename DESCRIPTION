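Package: sigCircuits
Title: Signaling-Circuit Activity Inference from Case/Control Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers changes in signaling-pathway function from case/control
    gene-expression data. Pathway topology is read from KEGG KGML files into
    signed directed graphs; normalized expression values are converted into
    per-gene presence (activation) probabilities with a per-probe
    two-component mixture model fitted on a reference compendium; exact
    receptor-to-effector signal-transmission probabilities are computed over
    each stimulus-response circuit by inclusion/exclusion under node
    independence; circuits whose transmission probability differs between
    conditions are detected with a rank-sum test and Benjamini-Hochberg FDR
    control. Includes a generator of synthetic pathways and expression studies
    with planted differential circuits for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
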