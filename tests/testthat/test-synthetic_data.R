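test_that("generators are pure functions of parameters and seed", {
  s <- introgression_scenario(n_demes = 2L, carrier_freq = c(0.3, 0.1),
                              n_diploids = c(8L, 8L), chrom_length = 1e6,
                              n_snps = 40L, focal_pos = 5e5, seed = 21L)
  a <- generate_introgression_dataset(s)
  b <- generate_introgression_dataset(s)
  expect_identical(a$haplotypes$haps, b$haplotypes$haps)
  expect_identical(a$truth$block_intervals, b$truth$block_intervals)
  s2 <- s; s2$seed <- 22L
  c_ <- generate_introgression_dataset(s2)
  expect_false(identical(a$haplotypes$haps, c_$haplotypes$haps))

  expect_identical(generate_alignment_set(seed = 9)$seqs,
                   generate_alignment_set(seed = 9)$seqs)
})

test_that("zero carrier frequency yields no carriers and a monomorphic focal SNP", {
  s <- introgression_scenario(n_demes = 2L, carrier_freq = c(0, 0),
                              n_diploids = c(10L, 10L), chrom_length = 1e6,
                              n_snps = 40L, focal_pos = 5e5, seed = 2L)
  sim <- generate_introgression_dataset(s)
  expect_true(all(sim$truth_labels == "hom_native"))
  expect_true(all(dosage(sim$genotypes)[, "snp_diag"] == 0))
  expect_true(all(is.na(sim$truth$block_intervals$start)))
})

test_that("every carrier block interval contains the focal position", {
  sim <- generate_introgression_dataset(introgression_scenario(
    n_demes = 1L, carrier_freq = 0.5, n_diploids = 30L, seed = 13L))
  bi <- sim$truth$block_intervals
  carr <- !is.na(bi$start)
  expect_gt(sum(carr), 0)
  expect_true(all(bi$start[carr] <= 3e6 & bi$end[carr] >= 3e6))
})

test_that("mean realized donor-block length matches the exponential model", {
  # Monte-Carlo oracle: one-sided lengths ~ Exp(mean = halflife), so the
  # expected total is 2 x halflife; use a long chromosome so truncation at
  # the ends is negligible
  halflife <- 375000
  lens <- unlist(lapply(1:100, function(s) {
    sim <- generate_introgression_dataset(introgression_scenario(
      n_demes = 1L, carrier_freq = 0.5, n_diploids = 10L,
      chrom_length = 2e7, n_snps = 5L, focal_pos = 1e7,
      block_halflife = halflife, seed = s))
    bi <- sim$truth$block_intervals
    bi$end[!is.na(bi$start)] - bi$start[!is.na(bi$start)]
  }))
  expect_gt(length(lens), 400)
  expect_lt(abs(mean(lens) - 2 * halflife) / (2 * halflife), 0.15)
})

test_that("infeasible carrier frequency warns and reports realized truth", {
  s <- introgression_scenario(n_demes = 1L, carrier_freq = 0.01,
                              n_diploids = 5L, chrom_length = 1e6,
                              n_snps = 10L, focal_pos = 5e5, seed = 1L)
  expect_warning(sim <- generate_introgression_dataset(s),
                 "realized frequency")
  expect_length(sim$truth$realized_carrier_freq, 1L)
})

test_that("alignment sets plant the exact divergence and donor differences", {
  aln <- generate_alignment_set(n_native = 7, n_carrier = 7, n_donor = 5,
                                length = 2253, native_carrier_divergence = 0.051,
                                donor_carrier_diffs = 5, seed = 2)
  pd <- p_distance(aln$seqs[["native_1"]], aln$seqs[["carrier_1"]])
  expect_equal(pd$n_diff, round(0.051 * 2253))      # 115 sites
  expect_equal(pd$distance, 115 / 2253)
  pi <- percent_identity(aln$seqs[["donor_1"]], aln$seqs[["carrier_1"]])
  expect_equal(pi$n_diff, 5L)
  expect_equal(pi$percent, 99.8)
  # within-group identity
  expect_identical(aln$seqs[["native_1"]], aln$seqs[["native_7"]])
  expect_identical(aln$seqs[["carrier_2"]], aln$seqs[["carrier_6"]])

  aln0 <- generate_alignment_set(native_carrier_divergence = 0, seed = 3)
  expect_identical(aln0$seqs[["native_1"]], aln0$seqs[["carrier_1"]])
  expect_error(generate_alignment_set(length = 10, donor_carrier_diffs = 11),
               "length|budget")
})

test_that("recombinant children are exact parent mosaics", {
  parents <- sequence_alignment(c(p1 = strrep("A", 100),
                                  p2 = strrep("C", 100)))
  out <- generate_recombinant_alignment(parents, breakpoints = 50L)
  child <- out$seqs[["recomb_1"]]
  expect_equal(substr(child, 1, 50), strrep("A", 50))
  expect_equal(substr(child, 51, 100), strrep("C", 50))

  copy <- generate_recombinant_alignment(parents, breakpoints = integer(0))
  expect_equal(unname(copy$seqs[["recomb_1"]]), unname(parents$seqs[["p1"]]))
  expect_error(generate_recombinant_alignment(parents, breakpoints = 100L),
               "outside")
  expect_error(generate_recombinant_alignment(parents, breakpoints = c(40L, 30L)),
               "increasing")
})

test_that("carrier-class heterozygosity is elevated only inside the block", {
  sim <- generate_introgression_dataset(introgression_scenario(seed = 31L))
  g <- sim$genotypes
  cl <- sim$truth_labels
  grp <- list(native = names(cl)[cl == "hom_native"],
              carrier = names(cl)[cl %in% c("het_carrier", "hom_introgressed")])
  inside <- g$map$id[abs(g$map$pos - 3e6) < 2e5]
  outside <- g$map$id[abs(g$map$pos - 3e6) > 1.5e6]
  he <- function(ids, who) {
    mean(vapply(ids, function(m) {
      expected_heterozygosity(g, m, grp[[who]])
    }, 0), na.rm = TRUE)
  }
  expect_gt(he(inside, "carrier"), he(inside, "native"))
  expect_lt(abs(he(outside, "carrier") - he(outside, "native")), 0.05)
})

test_that("the synthetic DRB panel carries its design constants", {
  p <- synthesize_drb_panel(seed = 8)
  expect_equal(n_sequences(p$ibex), 14L)
  expect_equal(p$ibex$length, 2253L)
  expect_equal(n_sequences(p$goats), 5L)
  expect_equal(length(suppressWarnings(informative_sites(p$ibex))), 116L)
  expect_equal(length(informative_sites(p$goats)), 64L)
})
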