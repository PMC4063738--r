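test_that("p-distance handles identity, simple differences and site masks", {
  expect_equal(p_distance("ACGT", "ACGT")$distance, 0)
  expect_equal(p_distance("ACGT", "ACGA")$distance, 0.25)
  expect_equal(p_distance("ACGT", "TGCA")$distance, 1)
  # gap and ambiguity excluded pairwise from numerator and denominator
  pd <- p_distance("AC-TN", "ACGTA")
  expect_equal(pd$sites_compared, 3L)
  expect_equal(pd$distance, 0)
  # ambiguity kept as literal state under the alternative policy
  pd2 <- p_distance("ACRT", "ACGT", ambiguity_policy = "ambiguity_as_state")
  expect_equal(pd2$sites_compared, 4L)
  expect_equal(pd2$n_diff, 1L)
  expect_error(p_distance("----", "ACGT"), "comparable")
  expect_error(p_distance("ACG", "ACGT"), "equal length")
  # symmetry
  a <- "ACGTTGCA"; b <- "ACCTTGGA"
  expect_equal(p_distance(a, b)$distance, p_distance(b, a)$distance)
})

test_that("distance_matrix equals the brute-force double loop", {
  set.seed(7)
  bases <- c("A", "C", "G", "T", "-", "N")
  seqs <- vapply(1:6, function(i) {
    paste(sample(bases, 40, replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
          collapse = "")
  }, "")
  names(seqs) <- paste0("t", 1:6)
  aln <- sequence_alignment(seqs)
  dm <- distance_matrix(aln)
  for (i in 1:5) for (j in (i + 1):6) {
    pd <- p_distance(seqs[i], seqs[j])
    expect_equal(dm$d[i, j], pd$distance)
    expect_equal(dm$n_sites[i, j], pd$sites_compared)
  }
  expect_true(isSymmetric(unname(dm$d)))
  expect_true(all(diag(dm$d) == 0))

  aln3 <- sequence_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_true(all(distance_matrix(aln3)$d == 0))
})

test_that("divergence summaries average pairwise distances with honest intervals", {
  # planted multiset {0.02, 0.10, 0.15} via a hand-built 3-taxon matrix
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D["a", "b"] <- D["b", "a"] <- 0.02
  D["a", "c"] <- D["c", "a"] <- 0.10
  D["b", "c"] <- D["c", "b"] <- 0.15
  s <- divergence_summary(as_distance_matrix(D))
  expect_equal(s$mean, 0.09)
  expect_equal(s$low, 0.02)     # inverse-ECDF percentiles hit min/max
  expect_equal(s$high, 0.15)

  D2 <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  s2 <- divergence_summary(as_distance_matrix(D2))
  expect_equal(c(s2$mean, s2$low, s2$high), c(0.1, 0.1, 0.1))

  # percentile interval stays within [min, max] and contains them for
  # small pair counts
  set.seed(1)
  vals <- runif(15)
  n <- 6
  M <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  M[upper.tri(M)] <- vals; M <- M + t(M)
  s3 <- divergence_summary(as_distance_matrix(M))
  expect_equal(s3$low, min(vals))
  expect_equal(s3$high, max(vals))
})

test_that("amino-acid divergence translates and masks codons correctly", {
  # synonymous-only: GGA/GGG both Gly
  expect_equal(aa_divergence("GGAGGA", "GGGGGG")$distance, 0)
  # one nonsynonymous change among 10 codons
  a <- strrep("GGA", 10)
  b <- paste0("CGA", strrep("GGA", 9))   # Arg vs Gly at codon 1
  r <- aa_divergence(a, b)
  expect_equal(r$distance, 0.1)
  expect_false(r$internal_stop)
  # internal stop flagged, not fatal
  r2 <- aa_divergence(paste0("TAA", strrep("GGA", 4)), strrep("GGA", 5))
  expect_true(r2$internal_stop)
  # codons containing gaps/ambiguity are excluded
  r3 <- aa_divergence("GG-GGA", "GGGGGA")
  expect_equal(r3$codons_compared, 1L)
  # frame offset
  expect_equal(aa_divergence(paste0("T", a), paste0("T", b),
                             frame_offset = 1)$distance, 0.1)

  # oracle: Biostrings translation on random clean sequences
  set.seed(42)
  for (k in 1:10) {
    n_codon <- sample(5:20, 1)
    s1 <- paste(sample(c("A", "C", "G", "T"), 3 * n_codon, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), 3 * n_codon, TRUE), collapse = "")
    aa1 <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(s1))), "")[[1]]
    aa2 <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(s2))), "")[[1]]
    expect_equal(aa_divergence(s1, s2)$distance, mean(aa1 != aa2))
  }
})

test_that("cross-species allele sharing equals brute-force comparison", {
  sets <- list(A = c(x = "ACGTAA", y = "CCGTAA"),
               B = c(u = "CCGTAA", v = "GGGTAA"))
  out <- find_shared_alleles(sets, 6)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, "CCGTAA")

  expect_equal(nrow(find_shared_alleles(
    list(A = c(a = "AAAA"), B = c(b = "CCCC")), 4)), 0L)

  # order invariance and brute-force oracle on 50 random sequences over 5 sets
  set.seed(30)
  pool <- vapply(1:12, function(i) {
    paste(sample(c("A", "C"), 8, TRUE), collapse = "")
  }, "")
  specs <- lapply(1:5, function(i) {
    s <- sample(pool, 10, replace = TRUE)
    names(s) <- paste0("q", seq_along(s)); s
  })
  names(specs) <- paste0("sp", 1:5)
  got <- find_shared_alleles(specs, 8)
  got_rev <- find_shared_alleles(rev(specs), 8)
  key <- function(df) sort(paste(df$species_a, df$species_b, df$sequence))
  expect_identical(key(got), key(got_rev))
  # brute force
  exp_rows <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    sh <- intersect(unique(specs[[i]]), unique(specs[[j]]))
    for (s in sh) exp_rows[[length(exp_rows) + 1L]] <-
        paste(paste0("sp", i), paste0("sp", j), s)
  }
  expect_identical(key(got), sort(unlist(exp_rows)))
})

test_that("percent identity matches the p-distance mask and reporting rules", {
  aln <- generate_alignment_set(length = 2253, donor_carrier_diffs = 5,
                                seed = 6)
  pi <- percent_identity(aln$seqs[["donor_1"]], aln$seqs[["carrier_1"]])
  expect_equal(pi$percent, 99.8)
  expect_equal(pi$n_diff, 5L)
  expect_equal(percent_identity("ACGT", "ACGT")$percent, 100.0)
  expect_equal(percent_identity("ACGT", "TGCA")$percent, 0.0)
  # identity = 100 * (1 - p-distance) under the same mask
  a <- "ACRT-GCA"; b <- "ACGTAGGA"
  expect_equal(percent_identity(a, b)$percent,
               round(100 * (1 - p_distance(a, b)$distance), 1))
})
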