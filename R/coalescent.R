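#' Coalescent haplotypes with a known population recombination rate
#'
#' Calibration-data generator: simulates a neutral coalescent with
#' recombination (via the \command{msprime} Python library, which must be
#' available on the \command{python} found on the PATH) so that the true
#' population recombination rate \code{rho = 4 * Ne * r} per bp is known
#' exactly. Used to validate the LD-decay fit's parameter recovery; it is
#' not part of the analysis pipeline itself.
#'
#' @param n_diploids diploid sample size (haplotypes = 2x).
#' @param length sequence length, bp.
#' @param Ne effective population size.
#' @param r per-bp recombination rate.
#' @param mu per-bp mutation rate.
#' @param max_snps keep at most this many (evenly thinned) biallelic SNPs.
#' @param seed integer seed.
#' @return a \code{HaplotypeMatrix}; \code{attr(, "rho")} holds the true
#'   rho per bp.
#' @export
simulate_coalescent_haplotypes <- function(n_diploids = 25L, length = 1e6,
                                           Ne = 1e4, r = 2.5e-9,
                                           mu = 2e-9, max_snps = 200L,
                                           seed = 1L) {
  py <- Sys.which("python")
  if (py == "") stop("python not found on PATH", call. = FALSE)
  out_file <- tempfile(fileext = ".tsv")
  script <- tempfile(fileext = ".py")
  writeLines(sprintf(
    'import msprime
import numpy as np
ts = msprime.sim_ancestry(samples=%d, ploidy=2, sequence_length=%g,
                          recombination_rate=%g, population_size=%g,
                          random_seed=%d)
mts = msprime.sim_mutations(ts, rate=%g, random_seed=%d,
                            model=msprime.BinaryMutationModel())
rows = []
seen = set()
for var in mts.variants():
    if len(var.alleles) != 2:
        continue
    p = int(round(var.site.position))
    if p in seen or p < 1:
        continue
    seen.add(p)
    rows.append((p, var.genotypes.copy()))
rows.sort(key=lambda t: t[0])
with open(%s, "w") as fh:
    for p, g in rows:
        fh.write(str(p) + "\\t" + "".join(map(str, g)) + "\\n")
', n_diploids, length, r, Ne, seed, mu, seed + 1L,
    deparse(out_file)), script)
  status <- system2(py, script, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out_file)) {
    stop("msprime simulation failed", call. = FALSE)
  }
  tab <- utils::read.table(out_file, header = FALSE, sep = "\t",
                           colClasses = "character")
  unlink(c(out_file, script))
  pos <- as.integer(tab[[1]])
  H <- t(vapply(strsplit(tab[[2]], "", fixed = TRUE),
                function(x) as.integer(x), integer(2L * n_diploids)))
  # thin evenly to max_snps polymorphic sites
  p <- colMeans(t(H))
  if (length(pos) > max_snps) {
    keep <- unique(round(seq(1L, length(pos), length.out = max_snps)))
    pos <- pos[keep]; H <- H[keep, , drop = FALSE]
  }
  map <- marker_map(sprintf("cs%05d", seq_along(pos)),
                    rep("sim1", length(pos)), pos)
  n_hap <- 2L * n_diploids
  sample_of <- rep(sprintf("cs_s%03d", seq_len(n_diploids)), each = 2L)
  hap_ids <- paste0(sample_of, rep(c("_A", "_B"), n_diploids))
  h <- haplotype_matrix(t(H), map, hap_ids, sample_of)
  attr(h, "rho") <- 4 * Ne * r
  h
}
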