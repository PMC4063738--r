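# shared fixture builders; everything is generated in code at test time

toy_alignment <- function(seqs) sequence_alignment(seqs)

# small diploid table with controllable missingness: geno is a samples x
# markers character matrix of "a/b" with "." for missing (alleles 0/1)
toy_genotypes <- function(geno, pos = NULL, chrom = "chr1", pop = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  a1 <- matrix(NA_integer_, n, m); a2 <- a1
  for (k in seq_len(m)) {
    parts <- strsplit(geno[, k], "/", fixed = TRUE)
    ok <- geno[, k] != "."
    a1[ok, k] <- as.integer(vapply(parts[ok], `[`, "", 1L))
    a2[ok, k] <- as.integer(vapply(parts[ok], `[`, "", 2L))
  }
  map <- marker_map(paste0("m", seq_len(m)), rep(chrom, m), pos)
  genotype_matrix(a1, a2, map,
                  sprintf("s%02d", seq_len(n)), pop)
}

# phased haplotypes from a plain 0/1 matrix (rows = haplotypes)
toy_haplotypes <- function(H, pos = NULL, chrom = "chr1", pop = NULL) {
  H <- as.matrix(H)
  if (is.null(pos)) pos <- seq_len(ncol(H)) * 1000L
  map <- marker_map(paste0("m", seq_len(ncol(H))), rep(chrom, ncol(H)), pos)
  sample_of <- sprintf("s%02d", ceiling(seq_len(nrow(H)) / 2))
  suffix <- rep_len(c("_A", "_B"), nrow(H))
  haplotype_matrix(H, map, paste0(sample_of, suffix), sample_of, pop)
}

# clonal (tree-evolved, finite-sites) alignment: homoplasy but no
# recombination; the null case for the Phi test
simulate_clonal_alignment <- function(seed, n_taxa = 12L, len = 300L,
                                      scale = 0.3) {
  set.seed(seed)
  tr <- ape::rcoal(n_taxa)
  tr$edge.length <- tr$edge.length /
    max(ape::node.depth.edgelength(tr)) * scale
  m <- toupper(as.character(phangorn::simSeq(tr, l = len)))
  sequence_alignment(stats::setNames(apply(m, 1, paste, collapse = ""),
                                     rownames(m)))
}

# random additive (tree) metric with its generating tree
random_tree_metric <- function(seed, n_taxa) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  o <- sort(rownames(D))
  list(tree = tr, d = as_distance_matrix(D[o, o]))
}

# brute-force EHH: fraction of carrier pairs identical over the full
# interval between the core and each flanking marker
brute_force_ehh <- function(h, core, allele) {
  mi <- match(core, h$map$id)
  if (is.na(mi)) mi <- core
  carriers <- which(h$haps[, mi] == allele)
  H <- h$haps[carriers, , drop = FALSE]
  n <- nrow(H)
  pairs <- utils::combn(n, 2)
  side <- function(idx_seq) {
    out <- data.frame(pos = h$map$pos[mi], ehh = 1)
    span <- mi
    for (j in idx_seq) {
      span <- c(span, j)
      ident <- mean(apply(pairs, 2, function(pr) {
        all(H[pr[1], span] == H[pr[2], span])
      }))
      out <- rbind(out, data.frame(pos = h$map$pos[j], ehh = ident))
    }
    out
  }
  list(left = side(rev(seq_len(mi - 1L))),
       right = side(seq_len(ncol(H))[-seq_len(mi)]))
}

# exhaustive minimum-homoplasy score for a pair of characters over all
# unrooted topologies (phangorn Fitch parsimony as the oracle)
brute_force_pair_score <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  labs <- paste0("t", seq_len(n))
  dat <- phangorn::phyDat(matrix(c(x, y), ncol = 2,
                                 dimnames = list(labs, NULL)),
                          type = "USER", levels = sort(unique(c(x, y))))
  trees <- phangorn::allTrees(n, tip.label = labs)
  best <- min(vapply(trees, function(tr) {
    sum(phangorn::parsimony(tr, dat, site = "site"))
  }, 0))
  k1 <- length(unique(x)); k2 <- length(unique(y))
  as.integer(best - (k1 - 1L) - (k2 - 1L))
}
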