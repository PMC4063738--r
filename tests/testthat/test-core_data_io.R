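test_that("FASTA alignments are read with the alignment contract enforced", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 extra tokens", "ACGTACGTAA", ">s2", "acgtacgtAA"), f)
  aln <- read_fasta_alignment(f)
  expect_s3_class(aln, "SequenceAlignment")
  expect_equal(aln$length, 10L)
  expect_equal(aln$names, c("s1", "s2"))
  expect_equal(unname(aln$seqs[2]), "ACGTACGTAA")  # case-normalized

  writeLines(c(">a", "ACGTACGTAA", ">b", "ACGTACGTA"), f)
  expect_error(read_fasta_alignment(f), "same length")
  writeLines(character(0), f)
  expect_error(read_fasta_alignment(f), "no records|FASTA")
  expect_error(read_fasta_alignment(tempfile()), "not found")
})

test_that("FASTA write/read round-trips byte-exactly", {
  aln <- generate_alignment_set(seed = 4)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta_alignment(aln, f1)
  write_fasta_alignment(read_fasta_alignment(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("minimal VCF and PLINK text read into genotype matrices", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB",
    "chr1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
    "chr1\t300\tsnp3\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|1"), f)
  g <- read_genotypes(f, "vcf")
  expect_equal(length(g$samples), 2L)
  expect_equal(nrow(g$map), 3L)
  expect_equal(unname(dosage(g)["sA", ]), c(0, 2, 1))
  expect_true(is.na(g$a1["sB", "snp2"]))

  ped <- withr::local_tempfile(fileext = ".ped")
  map <- sub("\\.ped$", ".map", ped)
  writeLines(c("chr1\tm1\t0\t100", "chr1\tm2\t0\t250"), map)
  writeLines(c("fam1\tp1\t0\t0\t0\t-9\tA\tA\tG\tT",
               "fam1\tp2\t0\t0\t0\t-9\tA\tG\t0\t0"), ped)
  gp <- read_genotypes(ped, "plink_text")
  expect_equal(length(gp$samples), 2L)
  expect_true(is.na(gp$a1["p2", "m2"]))   # "0 0" preserved as missing
  expect_false(anyNA(gp$a1["p1", ]))
})

test_that("generator output round-trips bit-exactly in every dialect", {
  sim <- generate_introgression_dataset(introgression_scenario(
    n_demes = 2L, carrier_freq = c(0.3, 0), n_diploids = c(6L, 6L),
    chrom_length = 5e5, n_snps = 30L, focal_pos = 2.5e5, seed = 11L))
  g <- sim$genotypes
  for (fmt in c("vcf", "plink_text", "tsv")) {
    ext <- c(vcf = ".vcf", plink_text = ".ped", tsv = ".tsv")[[fmt]]
    f1 <- withr::local_tempfile(fileext = ext)
    f2 <- withr::local_tempfile(fileext = ext)
    write_genotypes(g, f1, fmt)
    g2 <- read_genotypes(f1, fmt)
    write_genotypes(g2, f2, fmt)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(g2$map$pos, g$map$pos)
    if (fmt == "vcf") {
      # VCF carries ref/alt, so allele codes survive exactly
      expect_equal(unname(dosage(g2)), unname(dosage(g)))
    }
  }
})

test_that("sample call-rate filter keeps order and honors the threshold", {
  geno <- matrix("0/1", 3, 10)
  geno[2, 1:2] <- "."                     # 8/10 called
  g <- toy_genotypes(geno)
  gf <- filter_samples_by_call_rate(g, 0.9)
  expect_equal(gf$samples, c("s01", "s03"))
  expect_equal(attr(gf, "removed_samples"), "s02")
  expect_equal(filter_samples_by_call_rate(g, 0)$samples, g$samples)
  expect_error(filter_samples_by_call_rate(g, 1.5))
})

test_that("a 12-sample screen removes exactly the one sample below 90%", {
  geno <- matrix("0/1", 12, 20)
  geno[5, 1:3] <- "."                     # 17/20 = 85% called
  geno[7, 1] <- "."                       # 95% called, retained
  g <- toy_genotypes(geno)
  gf <- filter_samples_by_call_rate(g, 0.9)
  expect_equal(length(gf$samples), 11L)
  expect_false("s05" %in% gf$samples)
})

test_that("marker filters drop by call rate, MAF and obs-het-one with reasons", {
  # 10 markers, 20 samples; plant three failures
  geno <- matrix("0/0", 20, 10)
  geno[1:10, ] <- "0/1"                   # MAF 0.25 everywhere
  geno[1:14, 2] <- "."                    # marker 2: call rate 30%
  geno[, 3] <- "0/0"; geno[1, 3] <- "0/1" # marker 3: MAF 1/40 = 0.025 ok at 0.01
  geno[, 4] <- "0/0"                      # marker 4: monomorphic, MAF 0
  geno[, 5] <- "0/1"                      # marker 5: all-het
  g <- toy_genotypes(geno)
  gf <- filter_markers(g, min_call_rate = 0.7, min_maf = 0.01,
                       drop_obs_het_one = TRUE)
  log <- attr(gf, "filter_log")
  expect_equal(nrow(gf$map), 7L)
  expect_setequal(log$marker, c("m2", "m4", "m5"))
  expect_equal(log$reason[log$marker == "m2"], "call_rate")
  expect_equal(log$reason[log$marker == "m4"], "maf")
  expect_equal(log$reason[log$marker == "m5"], "obs_het_one")

  # single-marker MAF threshold example
  geno2 <- matrix("0/0", 100, 1); geno2[1, 1] <- "0/1"  # MAF 0.005
  g2 <- toy_genotypes(geno2)
  expect_equal(nrow(filter_markers(g2, min_maf = 0.01)$map), 0L)
})

test_that("filters are idempotent and the qc order is the documented one", {
  sim <- generate_introgression_dataset(introgression_scenario(
    n_demes = 1L, carrier_freq = 0.3, n_diploids = 20L,
    chrom_length = 1e6, n_snps = 50L, focal_pos = 5e5, seed = 3L))
  g <- sim$genotypes
  f1 <- filter_markers(g, min_maf = 0.05)
  f2 <- filter_markers(f1, min_maf = 0.05)
  expect_equal(f2$map$id, f1$map$id)
  expect_equal(unname(dosage(f2)), unname(dosage(f1)))

  # qc_genotypes applies sample call rate before marker filters: a marker
  # whose missingness is concentrated in a dropped sample can survive
  geno <- matrix("0/1", 10, 4)
  geno[1, ] <- "."                        # sample 1: 0% called
  geno[1, 2] <- "0/1"                     # marker 2 fully called otherwise
  g3 <- toy_genotypes(geno)
  q <- qc_genotypes(g3, sample_call_rate = 0.5, marker_call_rate = 0.95,
                    min_maf = 0, drop_obs_het_one = FALSE)
  expect_false("s01" %in% q$samples)
  expect_equal(nrow(q$map), 4L)           # marker rates are 100% post-drop
})

test_that("carrier classes follow the diagnostic-marker genotype", {
  geno <- rbind(c("1/1"), c("0/1"), c("0/0"), c("."))
  g <- toy_genotypes(geno)
  cl <- classify_carriers(g, "m1", 1L)
  expect_equal(as.character(cl),
               c("hom_introgressed", "het_carrier", "hom_native", "unknown"))
  expect_equal(names(cl), g$samples)

  sim <- generate_introgression_dataset(introgression_scenario(
    n_demes = 1L, carrier_freq = 0.31, n_diploids = 40L,
    chrom_length = 2e6, n_snps = 60L, focal_pos = 1e6, seed = 5L))
  cl2 <- classify_carriers(sim$genotypes, "snp_diag", 1L)
  expect_identical(as.character(cl2), as.character(sim$truth_labels))
})
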