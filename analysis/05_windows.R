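#!/usr/bin/env Rscript
# Sliding-window expected heterozygosity by carrier class (500 kb windows)
# and polymorphic SNP density per 100 kb, across the simulated chromosome.

suppressMessages(library(introsig))
out <- "results/windows"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- generate_introgression_dataset(introgression_scenario(seed = 1L))
g <- sim$genotypes
cl <- classify_carriers(g, "snp_diag", 1L)
grp <- list(native = names(cl)[cl == "hom_native"],
            carrier = names(cl)[cl %in% c("het_carrier", "hom_introgressed")])

region <- list("chr23", min(g$map$pos), max(g$map$pos))
he <- sliding_he(g, region, window_bp = 500000, step_bp = 100000,
                 groups = grp)
write_window_track(he, file.path(out, "sliding_he.tsv"))
write_window_track(he[he$group == "carrier", ],
                   file.path(out, "sliding_he_carrier.bedgraph"), "bedgraph")

dens <- snp_density(g$map, region, bin_bp = 100000, maf_threshold = 0.01,
                    g = g, groups = grp)
write_window_track(dens, file.path(out, "snp_density.tsv"))

inside <- he$start >= 2.625e6 & he$end <= 3.375e6 & he$n_snps > 0
mean_he <- tapply(he$value[inside], he$group[inside], mean, na.rm = TRUE)
cat(sprintf("mean He inside the donor-block region: carrier %.3f vs native %.3f\n",
            mean_he[["carrier"]], mean_he[["native"]]))
out_he <- tapply(he$value[!inside], he$group[!inside], mean, na.rm = TRUE)
cat(sprintf("outside: carrier %.3f vs native %.3f\n",
            out_he[["carrier"]], out_he[["native"]]))
cat("wrote", out, "\n")
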