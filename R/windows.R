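#' Expected heterozygosity of a marker within a sample group
#'
#' \code{He = 2p(1-p)} with p the allele frequency among called alleles in
#' the group; optionally the small-sample correction \code{2n/(2n-1)} is
#' applied. NA when the group has no called genotype at the marker.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param marker marker id or index.
#' @param group sample ids/indices (default all samples).
#' @param unbiased apply the \code{2n/(2n-1)} correction (off by default).
#' @return numeric He in [0, 0.5] (uncorrected).
#' @export
expected_heterozygosity <- function(g, marker, group = NULL,
                                    unbiased = FALSE) {
  mi <- marker_index(g$map, marker)
  gi <- group_index(g, group)
  a <- c(g$a1[gi, mi], g$a2[gi, mi])
  a <- a[!is.na(a)]
  if (!length(a)) return(NA_real_)
  p <- mean(a == 1L)
  he <- 2 * p * (1 - p)
  if (unbiased && length(a) > 1L) he <- he * length(a) / (length(a) - 1L)
  he
}

group_index <- function(g, group) {
  if (is.null(group)) return(seq_along(g$samples))
  if (is.character(group)) {
    gi <- match(group, g$samples)
    if (anyNA(gi)) stop("unknown sample in group", call. = FALSE)
    gi
  } else group
}

#' Sliding-window expected heterozygosity by group
#'
#' Tiles \code{region} with half-open windows \code{[start, start+window)}
#' advancing by \code{step_bp}, and reports the mean per-marker He per
#' window for each group of a carrier-class partition. Windows without
#' markers emit NA. The conventional scan uses 500 kb windows; the step
#' defaults to window/5 for smooth tracks.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param region list or vector (chrom, start, end).
#' @param window_bp window size, bp.
#' @param step_bp step, bp (must satisfy window >= step > 0).
#' @param groups a \code{CarrierLabels} factor or named list
#'   group -> sample ids; default one group of all samples.
#' @param unbiased see \code{\link{expected_heterozygosity}}.
#' @return a \code{WindowTrack} data.frame: chrom, start, end, group,
#'   value, n_snps.
#' @export
sliding_he <- function(g, region, window_bp = 500000,
                       step_bp = window_bp / 5, groups = NULL,
                       unbiased = FALSE) {
  stopifnot(window_bp >= step_bp, step_bp > 0)
  reg <- parse_region(region)
  grp <- parse_groups(g, groups)
  mi <- which(g$map$chrom == reg$chrom & g$map$pos >= reg$start &
                g$map$pos <= reg$end)
  starts <- seq(reg$start, max(reg$start, reg$end - 1), by = step_bp)
  out <- list()
  for (gname in names(grp)) {
    gi <- match(grp[[gname]], g$samples)
    for (st in starts) {
      in_w <- mi[g$map$pos[mi] >= st & g$map$pos[mi] < st + window_bp]
      he <- if (length(in_w)) {
        vals <- vapply(in_w, function(j) {
          expected_heterozygosity(g, j, gi, unbiased)
        }, 0)
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = reg$chrom, start = st, end = st + window_bp,
        group = gname, value = he, n_snps = length(in_w),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

parse_region <- function(region) {
  if (is.list(region)) {
    list(chrom = as.character(region[[1]]), start = as.numeric(region[[2]]),
         end = as.numeric(region[[3]]))
  } else {
    list(chrom = as.character(region[1]), start = as.numeric(region[2]),
         end = as.numeric(region[3]))
  }
}

parse_groups <- function(g, groups) {
  if (is.null(groups)) return(list(all = g$samples))
  if (inherits(groups, "CarrierLabels") || is.factor(groups)) {
    sp <- split(names(groups), as.character(groups))
    return(sp[lengths(sp) > 0])
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  groups
}

#' SNP density per bin by group
#'
#' Counts, per half-open bin anchored at the region start, the markers
#' polymorphic at \code{maf_threshold} or more within each group.
#'
#' @param map a \code{MarkerMap}.
#' @param region (chrom, start, end).
#' @param bin_bp bin width, bp.
#' @param maf_threshold minimum within-group MAF to count a marker.
#' @param g the \code{GenotypeMatrix} the MAF is computed from.
#' @param groups as in \code{\link{sliding_he}}.
#' @return a \code{WindowTrack} data.frame (value = count).
#' @export
snp_density <- function(map, region, bin_bp = 100000, maf_threshold = 0.01,
                        g, groups = NULL) {
  stopifnot(bin_bp > 0)
  reg <- parse_region(region)
  grp <- parse_groups(g, groups)
  starts <- seq(reg$start, max(reg$start, reg$end - 1), by = bin_bp)
  out <- list()
  for (gname in names(grp)) {
    gi <- match(grp[[gname]], g$samples)
    maf <- marker_maf(g, gi)
    poly <- !is.na(maf) & maf >= maf_threshold
    for (st in starts) {
      in_b <- map$chrom == reg$chrom & map$pos >= st & map$pos < st + bin_bp
      out[[length(out) + 1L]] <- data.frame(
        chrom = reg$chrom, start = st, end = st + bin_bp, group = gname,
        value = sum(in_b & poly), n_snps = sum(in_b),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a window track as BED-like TSV or BEDGRAPH
#' @param track a \code{WindowTrack} data.frame.
#' @param path output path.
#' @param format \code{"tsv"} (all columns) or \code{"bedgraph"}
#'   (chrom, 0-based start, end, value; one file per group expected).
#' @export
write_window_track <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(track, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  } else {
    bg <- data.frame(track$chrom, as.integer(track$start) - 1L,
                     as.integer(track$end), track$value)
    utils::write.table(bg, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
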