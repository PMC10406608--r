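Package: dollodyn
Title: Gene-Family Dynamics on Species Trees by Dollo Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs gene gain, duplication and loss histories across a
    species phylogeny from protein similarity networks. Builds homologous
    groups by coverage/e-value filtering, Markov clustering and profile-based
    cluster merging; roots and reconciles gene trees against the species tree
    by LCA mapping; delimits orthogroups and maps them onto species-tree
    branches by Dollo parsimony with integer copy-number parsimony; applies
    rule-based classifiers for conserved, novel-core, transcription-factor,
    transporter and small-secreted-protein repertoires; and summarises
    gene-content divergence by principal coordinate analysis with a minimum
    spanning tree and Fisher's exact GO enrichment. A synthetic-data module
    simulates gene-family evolution with known truth so every inference stage
    can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
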