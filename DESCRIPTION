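Package: introsig
Title: Detecting Recent Adaptive Introgression from Haplotype Signatures
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A population-genetic pipeline for detecting recent
    interspecific introgression of a haplotype block around a focal locus,
    motivated by the transfer of a domestic-goat MHC DRB haplotype into
    Alpine ibex. Implements raw p-distance and cross-species allele
    sharing on sequence alignments, the pairwise homoplasy index (Phi)
    recombination test with a site-permutation null, pairwise linkage
    disequilibrium (phased counting and genotype EM), LD-block
    classification and the Hill expected-r2 decay fit (rho = 4Ner),
    VIF-based marker pruning, extended haplotype homozygosity (EHH/iHH)
    and haplotype bifurcation trees, sliding-window expected
    heterozygosity and SNP density by carrier class, neighbor-joining
    trees and NeighborNet circular split networks with a haplotype
    cluster-cohesion score, plus seeded generators of synthetic
    introgression datasets and alignments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    ape,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
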