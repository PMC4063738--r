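#!/usr/bin/env Rscript
# Generate the default synthetic introgression dataset (4 demes, donor
# haplotype at frequencies 0.31/0.20/0.20/0.02, 750 kb expected donor block
# around the diagnostic SNP) and write it in the standard exchange formats.

suppressMessages(library(introsig))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenario <- introgression_scenario(seed = 1L)
sim <- generate_introgression_dataset(scenario)

write_genotypes(sim$genotypes, file.path(out, "genotypes.vcf"), "vcf")
write_genotypes(sim$genotypes, file.path(out, "genotypes.ped"), "plink_text")
write_haplotypes_vcf(sim$haplotypes, file.path(out, "haplotypes_phased.vcf"))
write_fasta_alignment(generate_alignment_set(seed = 1L),
                      file.path(out, "drb_alignment_synthetic.fasta"))
jsonlite::write_json(
  list(seed = sim$truth$seed,
       realized_carrier_freq = sim$truth$realized_carrier_freq,
       block_intervals = sim$truth$block_intervals,
       scenario = sim$truth$scenario[setdiff(names(sim$truth$scenario),
                                             character(0))]),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")

cl <- table(as.character(sim$truth_labels))
cat("samples:", length(sim$genotypes$samples),
    " markers:", nrow(sim$map), "\n")
cat("carrier classes:", paste(names(cl), cl, sep = "=", collapse = "  "), "\n")
cat("realized donor-haplotype frequencies per deme:",
    round(sim$truth$realized_carrier_freq, 3), "\n")
cat("wrote", out, "\n")
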