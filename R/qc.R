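#' Filter samples by genotyping call rate
#'
#' Retains samples whose fraction of non-missing genotypes is at least
#' \code{min_rate}; sample order is preserved. A 90\% per-individual rate is
#' the usual screen for chip data; RAD data are typically screened at the
#' marker level instead.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param min_rate minimum fraction called, in [0, 1].
#' @return filtered \code{GenotypeMatrix}; the removed sample ids are in
#'   \code{attr(, "removed_samples")}.
#' @export
filter_samples_by_call_rate <- function(g, min_rate) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  rate <- rowMeans(!is.na(g$a1))
  keep <- rate >= min_rate
  if (!any(keep)) warning("all samples removed by call-rate filter")
  out <- subset_genotypes(g, samples = which(keep))
  attr(out, "removed_samples") <- g$samples[!keep]
  out
}

#' Filter markers by call rate, MAF and all-heterozygous state
#'
#' Drops markers failing (in this order) per-marker call rate, minor allele
#' frequency computed on called alleles, and — when
#' \code{drop_obs_het_one} — markers at which every called genotype is
#' heterozygous. An observed heterozygosity of one is a hallmark of collapsed
#' duplicated regions rather than a real segregating site. A per-marker
#' filter log (marker id, reason) is attached.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param min_call_rate minimum fraction of samples called.
#' @param min_maf minimum minor allele frequency.
#' @param drop_obs_het_one drop markers with observed heterozygosity 1.
#' @return filtered \code{GenotypeMatrix} with \code{attr(, "filter_log")}.
#' @export
filter_markers <- function(g, min_call_rate = 0, min_maf = 0,
                           drop_obs_het_one = FALSE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  n_mark <- nrow(g$map)
  reason <- rep(NA_character_, n_mark)

  called <- !is.na(g$a1)
  call_rate <- colMeans(called)
  reason[is.na(reason) & call_rate < min_call_rate] <- "call_rate"

  maf <- marker_maf(g)
  reason[is.na(reason) & (is.na(maf) | maf < min_maf)] <- "maf"

  if (drop_obs_het_one) {
    het <- g$a1 != g$a2
    all_het <- colSums(het, na.rm = TRUE) == colSums(called) &
      colSums(called) > 0
    reason[is.na(reason) & all_het] <- "obs_het_one"
  }

  keep <- is.na(reason)
  out <- subset_genotypes(g, markers = which(keep))
  attr(out, "filter_log") <- data.frame(
    marker = g$map$id[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Minor allele frequency per marker (called alleles only)
#' @param g a \code{GenotypeMatrix}.
#' @param samples optional subset of sample ids/indices.
#' @return numeric vector, NA where no alleles are called.
#' @export
marker_maf <- function(g, samples = NULL) {
  if (!is.null(samples)) g <- subset_genotypes(g, samples = samples)
  p <- allele1_freq(g)
  pmin(p, 1 - p)
}

# frequency of allele code 1 on called alleles (biallelic markers)
allele1_freq <- function(g) {
  n1 <- colSums(g$a1 == 1L, na.rm = TRUE) + colSums(g$a2 == 1L, na.rm = TRUE)
  n <- colSums(!is.na(g$a1)) * 2L
  ifelse(n == 0L, NA_real_, n1 / n)
}

#' Standard QC in the documented fixed order
#'
#' Applies sample call rate, then marker call rate, then MAF, then the
#' all-heterozygous exclusion. The order matters (sample removal changes
#' marker rates) and is pinned by regression tests.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param sample_call_rate,marker_call_rate,min_maf thresholds in [0,1].
#' @param drop_obs_het_one drop all-heterozygous markers.
#' @return filtered \code{GenotypeMatrix}; \code{attr(, "qc_log")} holds the
#'   per-step logs.
#' @export
qc_genotypes <- function(g, sample_call_rate = 0.9, marker_call_rate = 0.9,
                         min_maf = 0.01, drop_obs_het_one = TRUE) {
  g1 <- filter_samples_by_call_rate(g, sample_call_rate)
  removed <- attr(g1, "removed_samples")
  g2 <- filter_markers(g1, min_call_rate = marker_call_rate,
                       min_maf = min_maf,
                       drop_obs_het_one = drop_obs_het_one)
  attr(g2, "qc_log") <- list(removed_samples = removed,
                             marker_log = attr(g2, "filter_log"))
  g2
}

#' Classify samples by diagnostic-marker genotype
#'
#' The carrier classes follow the dose of the introgressed allele at a
#' diagnostic biallelic SNP: 0 copies = \code{hom_native}, 1 =
#' \code{het_carrier}, 2 = \code{hom_introgressed}; missing genotypes are
#' \code{unknown}.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param diagnostic_marker marker id.
#' @param introgressed_allele allele code (0/1) of the introgressed allele.
#' @return a \code{CarrierLabels}: named factor (sample -> class).
#' @export
classify_carriers <- function(g, diagnostic_marker, introgressed_allele = 1L) {
  j <- match(diagnostic_marker, g$map$id)
  if (is.na(j)) stop("diagnostic marker not found: ", diagnostic_marker,
                     call. = FALSE)
  if (grepl(",", g$map$alt[j])) {
    stop("diagnostic marker must be biallelic", call. = FALSE)
  }
  copies <- (g$a1[, j] == introgressed_allele) +
    (g$a2[, j] == introgressed_allele)
  cls <- c("hom_native", "het_carrier", "hom_introgressed")[copies + 1L]
  cls[is.na(copies)] <- "unknown"
  f <- factor(cls, levels = c("hom_native", "het_carrier",
                              "hom_introgressed", "unknown"))
  names(f) <- g$samples
  class(f) <- c("CarrierLabels", "factor")
  f
}
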