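Package: rhodup
Title: Duplication and Loss History of the Teleost Rhodopsin Gene Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the duplication and loss history of the
    rod opsin (rh1) gene family in teleost fishes. Provides an RY-recoding and
    base-composition toolkit for in-frame coding alignments, a GTR+Gamma
    maximum-likelihood engine (Felsenstein pruning with IUPAC ambiguity,
    discrete gamma rates, branch-length and model optimisation), constrained
    topology search with nonparametric bootstrap, RELL and approximately
    unbiased (AU) topology tests over candidate duplication/loss hypotheses,
    LCA gene-tree/species-tree reconciliation with duplication and loss
    counting, Fitch parsimony ancestral-state reconstruction of opsin gene
    characters, spectral-tuning key-site comparison between paralogs in bovine
    rhodopsin numbering, and a synthetic gene-family generator so the whole
    chain can be exercised without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
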