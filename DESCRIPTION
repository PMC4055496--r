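Package: fishaudit
Title: Seafood Authentication by Real-Time PCR and COI Barcoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for auditing the species labelling of retail seafood with
    two DNA-based assays: endpoint real-time PCR species calls against a
    no-template-control threshold (z*M = M + 3.89*SD + C), and COI barcode
    assignment by pairwise sequence identity against a species-labelled
    reference panel with congener-group and mixed-composition rules. Includes
    a neighbour-joining tree builder with bootstrap supports, label-versus-
    genetics concordance with stratified mislabelling rates and quota
    extrapolation, and a synthetic-data generator (gadoid-like COI panels,
    replicate queries, chimeric products, plate fluorescence) so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
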