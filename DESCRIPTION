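Package: paleoploid
Title: Macrosynteny-Based Detection of Ancient Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects an ancient whole-genome duplication (WGD) shared by a
    clade from chromosome-scale gene orders and all-vs-all similarity hits.
    Implements reciprocal-best-hit paralog pairing with an e-value threshold,
    synonymous-distance (Ks) estimation by the Nei-Gojobori (1986) counting
    method with Jukes-Cantor correction, the same-chromosome exclusion filter,
    and BIC-selected Gaussian-mixture peak counting on log-Ks; calibrates
    genomes against ancestral chromosomes via outgroup proxy genes, isolates
    and clusters syntenic segments, reassembles them into ancestral-chromosome
    coordinates, selects ancestral genes with homologs on exactly two segments
    per species, and classifies per-chromosome duplicate gene trees as shared
    versus independent duplications by quartet topology votes. Ships a forward
    simulator of genome evolution (speciation, optional WGD with fractionation,
    tandem and dispersed small-scale duplication, gene loss, chromosome fission
    and fusion, lognormal-noised divergence) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
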