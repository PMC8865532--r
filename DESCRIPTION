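Package: mycomine
Title: Genome Feature Mining and Expression Filtering for Fungal Assemblies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining structural and functional features of
    telomere-to-telomere fungal genome assemblies: prediction of CAZyme gene
    clusters (physically linked carbohydrate-active-enzyme loci akin to
    polysaccharide utilization loci) by an intergenic-distance linkage rule,
    telomere motif detection, centromere-candidate calling from ORF-free
    repeat-dense intervals, repeat-hit confidence filtering and density tracks,
    banded mitogenome comparison with per-base error rates, rDNA copy-ratio
    estimation from coverage, TPM/RPK/FPKM quantification, Fisher-exact
    differential expression with Benjamini-Hochberg FDR, fruiting-related-gene
    and ortholog-overlap classification, and lncRNA/effector candidate filter
    cascades. Seeded simulators generate every input with machine-readable
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    igraph,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
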