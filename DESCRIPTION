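Package: chaperflux
Title: Chaperone Network Workload and SILAC Quantification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis of chaperone deletion mutants in yeast:
    SILAC heavy/light ratio statistics with linear-regression normalization
    and global cell-size shift estimation, chaperome network perturbation by
    in silico node deletion with per-node topology metrics (degree,
    neighborhood connectivity, clustering coefficient, component-normalized
    betweenness centrality), and a chaperone folding-workload model that
    converts protein abundance and turnover into per-chaperone synthesis
    flux and redistributes it after a deletion. Includes a synthetic-data
    generator emulating hub-dominated chaperone-substrate networks and
    replicate SILAC experiments so the full pipeline is testable without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
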