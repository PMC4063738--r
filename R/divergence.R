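#' Raw p-distance between two aligned sequences
#'
#' Proportion of compared sites that differ — no substitution-model
#' correction. Under the default \code{pairwise_deletion} policy a site is
#' excluded from numerator and denominator whenever either sequence carries
#' a gap or an ambiguity code; under \code{ambiguity_as_state} only gaps are
#' excluded and ambiguity codes compare as literal states. Pairwise deletion
#' keeps heterozygous-position ambiguity codes (common in directly sequenced
#' goat samples) from inflating distances.
#'
#' @param a,b equal-length sequences (character scalars or character
#'   vectors of single characters).
#' @param ambiguity_policy \code{"pairwise_deletion"} or
#'   \code{"ambiguity_as_state"}.
#' @return list with \code{distance}, \code{n_diff}, \code{sites_compared}.
#' @export
p_distance <- function(a, b,
                       ambiguity_policy = c("pairwise_deletion",
                                            "ambiguity_as_state")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  av <- as_chars(a); bv <- as_chars(b)
  if (length(av) != length(bv)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  keep <- if (ambiguity_policy == "pairwise_deletion") {
    is_acgt(av) & is_acgt(bv)
  } else {
    !is_gap(av) & !is_gap(bv)
  }
  n <- sum(keep)
  if (n == 0L) stop("no comparable sites between sequences", call. = FALSE)
  nd <- sum(av[keep] != bv[keep])
  list(distance = nd / n, n_diff = nd, sites_compared = n)
}

as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) {
    strsplit(toupper(x), "", fixed = TRUE)[[1]]
  } else toupper(x)
}

#' Pairwise p-distance matrix for an alignment
#'
#' @param aln a \code{SequenceAlignment} of at least 2 sequences.
#' @param ambiguity_policy see \code{\link{p_distance}}.
#' @return a \code{DistanceMatrix}: list with symmetric \code{d} (raw
#'   p-distances), \code{n_sites} (per-pair compared sites) and \code{taxa}.
#' @export
distance_matrix <- function(aln, ambiguity_policy = "pairwise_deletion") {
  stopifnot(inherits(aln, "SequenceAlignment"))
  n <- n_sequences(aln)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  m <- alignment_matrix(aln)
  ok <- if (ambiguity_policy == "pairwise_deletion") {
    matrix(is_acgt(m), nrow(m))
  } else {
    matrix(!is_gap(m), nrow(m))
  }
  d <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  ns <- matrix(aln$length, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- ok[i, ] & ok[j, ]
      nc <- sum(keep)
      if (nc == 0L) {
        stop("no comparable sites between ", aln$names[i], " and ",
             aln$names[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(m[i, keep] != m[j, keep]) / nc
      ns[i, j] <- ns[j, i] <- nc
    }
  }
  structure(list(d = d, n_sites = ns, taxa = aln$names),
            class = "DistanceMatrix")
}

#' Build a DistanceMatrix from a plain symmetric matrix
#' @param d symmetric numeric matrix with dimnames.
#' @export
as_distance_matrix <- function(d) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  structure(list(d = d, n_sites = NULL, taxa = rownames(d)),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("DistanceMatrix over", length(x$taxa), "taxa; mean off-diagonal",
      format(mean(x$d[upper.tri(x$d)]), digits = 4), "\n")
  invisible(x)
}

#' Summarize allele divergence
#'
#' Mean pairwise p-distance over all off-diagonal pairs, with an interval.
#' The default interval is the empirical 2.5/97.5 percentile range of the
#' pairwise distances (inverse-ECDF quantiles, so small pair sets yield the
#' min/max); \code{"bootstrap"} gives a percentile bootstrap of the mean.
#'
#' @param d a \code{DistanceMatrix}.
#' @param interval_method \code{"percentile"} or \code{"bootstrap"}.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return list with \code{mean}, \code{low}, \code{high}, \code{n_alleles},
#'   \code{n_pairs}.
#' @export
divergence_summary <- function(d, interval_method = c("percentile",
                                                      "bootstrap"),
                               n_boot = 2000L, seed = 1L) {
  interval_method <- match.arg(interval_method)
  stopifnot(inherits(d, "DistanceMatrix"))
  vals <- d$d[upper.tri(d$d)]
  if (length(vals) < 1L) stop("need at least 2 taxa", call. = FALSE)
  m <- mean(vals)
  if (interval_method == "percentile" || length(vals) == 1L) {
    q <- stats::quantile(vals, c(0.025, 0.975), type = 1, names = FALSE)
  } else {
    local_rng(seed)
    bm <- replicate(n_boot, mean(sample(vals, replace = TRUE)))
    q <- stats::quantile(bm, c(0.025, 0.975), type = 1, names = FALSE)
  }
  list(mean = m, low = q[1], high = q[2],
       n_alleles = length(d$taxa), n_pairs = length(vals))
}

#' Amino-acid p-distance between two aligned coding sequences
#'
#' Translates both sequences in the given frame with the standard genetic
#' code, truncates to whole codons, and computes the proportion of differing
#' amino acids. Codons containing gaps or ambiguity in either sequence are
#' excluded. Internal stop codons are flagged, not fatal.
#'
#' @param a,b equal-length nucleotide sequences.
#' @param frame_offset 0, 1 or 2 bases to skip before the first codon.
#' @return list with \code{distance}, \code{n_diff}, \code{codons_compared},
#'   \code{internal_stop} (logical).
#' @export
aa_divergence <- function(a, b, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  av <- as_chars(a); bv <- as_chars(b)
  if (length(av) != length(bv)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (frame_offset > 0L) {
    av <- av[-seq_len(frame_offset)]
    bv <- bv[-seq_len(frame_offset)]
  }
  n_codon <- length(av) %/% 3L
  if (n_codon < 1L) stop("fewer than one codon after frame offset",
                         call. = FALSE)
  idx <- seq_len(3L * n_codon)
  translate1 <- function(x) {
    cm <- matrix(x[idx], nrow = 3L)
    codons <- apply(cm, 2L, paste, collapse = "")
    ok <- !grepl("[^ACGT]", codons)
    aa <- rep(NA_character_, n_codon)
    aa[ok] <- unname(Biostrings::GENETIC_CODE[codons[ok]])
    aa
  }
  aa_a <- translate1(av); aa_b <- translate1(bv)
  keep <- !is.na(aa_a) & !is.na(aa_b)
  if (!any(keep)) stop("no comparable codons", call. = FALSE)
  # a terminal stop is expected; flag stops before the last codon
  internal_stop <- any(which(aa_a == "*" | aa_b == "*") < n_codon,
                       na.rm = TRUE)
  nd <- sum(aa_a[keep] != aa_b[keep])
  list(distance = nd / sum(keep), n_diff = nd,
       codons_compared = sum(keep), internal_stop = internal_stop)
}

#' Cross-species shared alleles on a trimmed window
#'
#' Trims every sequence to \code{trim_length}, removes within-species
#' duplicates, and reports every cross-species pair of species whose trimmed
#' sequences are exactly identical — the operational definition of
#' cross-species allele sharing on a universal fragment length.
#'
#' @param species_sets named list: species -> named character vector of
#'   sequences.
#' @param trim_length window length; all sequences must be at least this
#'   long.
#' @return data.frame with columns \code{species_a}, \code{species_b},
#'   \code{sequence} (one row per shared allele and species pair, species
#'   pair ordered alphabetically).
#' @export
find_shared_alleles <- function(species_sets, trim_length) {
  stopifnot(is.list(species_sets), length(species_sets) >= 2L)
  trimmed <- lapply(species_sets, function(ss) {
    ss <- toupper(as.character(ss))
    if (any(nchar(ss) < trim_length)) {
      stop("all sequences must be at least trim_length long", call. = FALSE)
    }
    unique(substr(ss, 1L, trim_length))
  })
  species <- sort(names(trimmed))
  out <- list()
  for (i in seq_along(species)[-length(species)]) {
    for (j in (i + 1L):length(species)) {
      shared <- intersect(trimmed[[species[i]]], trimmed[[species[j]]])
      if (length(shared)) {
        out[[length(out) + 1L]] <- data.frame(
          species_a = species[i], species_b = species[j],
          sequence = sort(shared), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(species_a = character(), species_b = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Percent identity between two aligned sequences
#'
#' \code{100 * (1 - differing / compared)} under the same site mask as
#' \code{\link{p_distance}}, reported half-up to one decimal, with the
#' companion count of differing sites.
#'
#' @inheritParams p_distance
#' @return list with \code{percent} (one decimal), \code{n_diff},
#'   \code{sites_compared}.
#' @export
percent_identity <- function(a, b, ambiguity_policy = "pairwise_deletion") {
  pd <- p_distance(a, b, ambiguity_policy)
  list(percent = round_half_up(100 * (1 - pd$distance), 1L),
       n_diff = pd$n_diff, sites_compared = pd$sites_compared)
}

# round half away from zero (reporting convention for percentages)
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Export a distance matrix
#' @param d a \code{DistanceMatrix}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"phylip"} (square).
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(d$d, path, quote = FALSE, sep = "\t",
                       col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(d$taxa)), con)
    for (i in seq_along(d$taxa)) {
      writeLines(paste(formatC(d$taxa[i], width = -10),
                       paste(sprintf("%.6f", d$d[i, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
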