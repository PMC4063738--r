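#' Marker map
#'
#' Physical positions of markers on chromosomes, 1-based bp (VCF convention).
#' Positions must be strictly increasing within each chromosome and marker
#' ids unique. For biallelic SNPs \code{ref}/\code{alt} give the two alleles
#' coded 0 and 1; multi-allelic markers list alleles comma-separated in
#' \code{alt} (codes 0, 1, 2, ... in ref-then-alt order).
#'
#' @param id character marker ids.
#' @param chrom character chromosome labels.
#' @param pos integer positions, bp, 1-based.
#' @param ref,alt allele strings.
#' @return a \code{MarkerMap} (data.frame subclass).
#' @export
marker_map <- function(id, chrom, pos, ref = "A", alt = "G") {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   pos = as.integer(pos), ref = as.character(ref),
                   alt = as.character(alt), stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("marker ids must be unique", call. = FALSE)
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  class(df) <- c("MarkerMap", "data.frame")
  df
}

marker_alleles <- function(map, i) {
  c(map$ref[i], strsplit(map$alt[i], ",", fixed = TRUE)[[1]])
}

#' Diploid genotype matrix
#'
#' Unphased diploid genotypes as two allele-code matrices (samples x markers);
#' alleles are integer codes into the marker's allele list (0 = ref). Missing
#' genotypes are \code{NA} in both allele slots. Carries its \code{MarkerMap}
#' and per-sample population labels.
#'
#' @param a1,a2 integer matrices (samples x markers) of allele codes.
#' @param map a \code{MarkerMap} with one row per column of \code{a1}.
#' @param samples character sample ids.
#' @param pop character population label per sample.
#' @return a \code{GenotypeMatrix}.
#' @export
genotype_matrix <- function(a1, a2, map, samples, pop = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)), nrow(map) == ncol(a1),
            length(samples) == nrow(a1))
  if (anyDuplicated(samples)) stop("sample ids must be unique", call. = FALSE)
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing genotypes are not supported", call. = FALSE)
  }
  if (is.null(pop)) pop <- rep("pop1", length(samples))
  nall <- nchar(gsub("[^,]", "", map$alt)) + 2L  # ref + alts
  maxcode <- suppressWarnings(
    pmax(apply(a1, 2, max, na.rm = TRUE), apply(a2, 2, max, na.rm = TRUE)))
  maxcode[!is.finite(maxcode)] <- 0
  if (any(maxcode > nall - 1L) || min(a1, a2, 0, na.rm = TRUE) < 0) {
    stop("allele codes out of range for marker allele lists", call. = FALSE)
  }
  dimnames(a1) <- dimnames(a2) <- list(samples, map$id)
  structure(list(a1 = a1, a2 = a2, map = map,
                 samples = as.character(samples),
                 pop = stats::setNames(as.character(pop), samples)),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$samples), "samples x", nrow(x$map),
      "markers;", length(unique(x$pop)), "population(s)\n")
  invisible(x)
}

#' Allele dosage matrix (count of allele 1; biallelic markers)
#' @param g a \code{GenotypeMatrix}.
#' @export
dosage <- function(g) g$a1 + g$a2

#' Phased haplotype matrix
#'
#' Phased haplotypes (2 per diploid sample, suffixes \code{_A}/\code{_B}) as
#' an integer allele-code matrix with no missing values. The phased-input
#' contract means every downstream computation (LD, EHH, networks) can assume
#' complete data.
#'
#' @param haps integer matrix (haplotypes x markers), no NA.
#' @param map a \code{MarkerMap}.
#' @param hap_ids haplotype ids.
#' @param sample_of character sample id per haplotype.
#' @param pop population label per haplotype.
#' @return a \code{HaplotypeMatrix}.
#' @export
haplotype_matrix <- function(haps, map, hap_ids, sample_of, pop = NULL) {
  haps <- as.matrix(haps)
  stopifnot(nrow(map) == ncol(haps), length(hap_ids) == nrow(haps),
            length(sample_of) == nrow(haps))
  if (anyNA(haps)) stop("HaplotypeMatrix must not contain missing values",
                        call. = FALSE)
  if (anyDuplicated(hap_ids)) stop("haplotype ids must be unique",
                                   call. = FALSE)
  if (is.null(pop)) pop <- rep("pop1", nrow(haps))
  dimnames(haps) <- list(hap_ids, map$id)
  structure(list(haps = haps, map = map, hap_ids = as.character(hap_ids),
                 sample_of = stats::setNames(as.character(sample_of), hap_ids),
                 pop = stats::setNames(as.character(pop), hap_ids)),
            class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat("HaplotypeMatrix:", nrow(x$haps), "haplotypes x", ncol(x$haps),
      "markers\n")
  invisible(x)
}

#' Collapse phased haplotypes to unphased genotypes
#' @param h a \code{HaplotypeMatrix}.
#' @export
as_genotypes <- function(h) {
  samples <- unique(unname(h$sample_of))
  idx <- split(seq_along(h$sample_of), h$sample_of)[samples]
  if (any(lengths(idx) != 2L)) {
    stop("each sample must have exactly two haplotypes", call. = FALSE)
  }
  a1 <- h$haps[vapply(idx, `[`, 1L, 1L), , drop = FALSE]
  a2 <- h$haps[vapply(idx, `[`, 2L, 2L), , drop = FALSE]
  pop <- h$pop[vapply(idx, `[`, 1L, 1L)]
  genotype_matrix(a1, a2, h$map, samples, unname(pop))
}

## ---------------------------------------------------------------------------
## Reading genotypes

#' Read diploid genotypes
#'
#' Supported dialects: VCF v4.x (GT field only, via \pkg{vcfR}), PLINK text
#' \code{.ped}/\code{.map} pairs, and a flat TSV dialect with columns
#' \code{sample}, \code{marker}, \code{allele1}, \code{allele2} (alleles as
#' bases; \code{0} = missing, PLINK convention). Biallelic SNP alleles are
#' mapped to codes 0/1 by ref/alt; missing genotypes are preserved as NA.
#'
#' @param path input path. For \code{plink_text} give the \code{.ped} path;
#'   the \code{.map} is found by extension substitution. PLINK and TSV
#'   dialects carry no ref/alt designation, so alleles are coded
#'   alphabetically (ref = alphabetically first observed allele).
#' @param format one of \code{"vcf"}, \code{"plink_text"}, \code{"tsv"}.
#' @return a \code{GenotypeMatrix}.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink_text = read_genotypes_plink(path),
         tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate marker id in VCF", call. = FALSE)
  map <- marker_map(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                    fix[, "REF"], fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(gt)
  parse_allele <- function(x) {
    x[x == "."] <- NA
    suppressWarnings(as.integer(x))
  }
  parts <- strsplit(ifelse(is.na(gt), ".|.", gt), "[/|]")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("non-diploid GT entry in VCF", call. = FALSE)
  m <- matrix(unlist(parts), nrow = 2L)
  a1 <- matrix(parse_allele(m[1, ]), nrow = nrow(gt), ncol = ncol(gt))
  a2 <- matrix(parse_allele(m[2, ]), nrow = nrow(gt), ncol = ncol(gt))
  both_na <- is.na(a1) | is.na(a2)
  a1[both_na] <- NA; a2[both_na] <- NA
  genotype_matrix(t(a1), t(a2), map, samples)
}

read_genotypes_plink <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path) || !file.exists(map_path)) {
    stop("matching .map file not found for ", ped_path, call. = FALSE)
  }
  mp <- utils::read.table(map_path, header = FALSE,
                          col.names = c("chrom", "id", "cm", "pos"),
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L + 2L * nrow(mp)) {
    stop(".ped column count does not match .map marker count", call. = FALSE)
  }
  samples <- ped[[2]]
  pop <- ped[[1]]
  am <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1c <- am[, seq(1L, ncol(am), by = 2L), drop = FALSE]
  a2c <- am[, seq(2L, ncol(am), by = 2L), drop = FALSE]
  a1c[a1c == "0"] <- NA; a2c[a2c == "0"] <- NA
  both_na <- is.na(a1c) | is.na(a2c)
  a1c[both_na] <- NA; a2c[both_na] <- NA
  # infer ref/alt per marker: ref = first allele seen scanning samples
  n_mark <- nrow(mp)
  a1 <- matrix(NA_integer_, nrow(a1c), n_mark)
  a2 <- a1
  ref <- alt <- character(n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1c[, j], a2c[, j])
    alleles <- sort(unique(obs[!is.na(obs)]))  # alphabetical: ref = first
    if (any(!alleles %in% c("A", "C", "G", "T"))) {
      stop("unknown allele symbol at marker ", mp$id[j], call. = FALSE)
    }
    if (length(alleles) > 2L) {
      stop("more than two alleles at SNP ", mp$id[j], call. = FALSE)
    }
    if (length(alleles) == 0L) alleles <- c("A", "G")
    if (length(alleles) == 1L) {
      alleles <- c(alleles, setdiff(c("A", "C", "G", "T"), alleles)[1])
    }
    ref[j] <- alleles[1]; alt[j] <- alleles[2]
    a1[, j] <- match(a1c[, j], alleles) - 1L
    a2[, j] <- match(a2c[, j], alleles) - 1L
  }
  ord <- order(mp$chrom, mp$pos)
  map <- marker_map(mp$id[ord], mp$chrom[ord], mp$pos[ord],
                    ref[ord], alt[ord])
  genotype_matrix(a1[, ord, drop = FALSE], a2[, ord, drop = FALSE],
                  map, samples, pop)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("sample", "marker", "chrom", "pos", "allele1", "allele2")
  if (!all(need %in% names(tab))) {
    stop("TSV dialect needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mk <- unique(tab[, c("marker", "chrom", "pos")])
  if (anyDuplicated(mk$marker)) {
    stop("duplicate marker id with conflicting map entries", call. = FALSE)
  }
  ord <- order(mk$chrom, as.integer(mk$pos))
  mk <- mk[ord, ]
  samples <- unique(tab$sample)
  a1 <- matrix(NA_integer_, length(samples), nrow(mk))
  a2 <- a1
  ref <- alt <- character(nrow(mk))
  for (j in seq_len(nrow(mk))) {
    rows <- tab[tab$marker == mk$marker[j], ]
    al <- c(rows$allele1, rows$allele2)
    al[al == "0"] <- NA
    alleles <- sort(unique(al[!is.na(al)]))    # alphabetical: ref = first
    if (any(!alleles %in% c("A", "C", "G", "T"))) {
      stop("unknown allele symbol at marker ", mk$marker[j], call. = FALSE)
    }
    if (length(alleles) == 0L) alleles <- c("A", "G")
    if (length(alleles) == 1L) {
      alleles <- c(alleles, setdiff(c("A", "C", "G", "T"), alleles)[1])
    }
    if (length(alleles) > 2L) {
      stop("more than two alleles at SNP ", mk$marker[j], call. = FALSE)
    }
    ref[j] <- alleles[1]; alt[j] <- alleles[2]
    i <- match(rows$sample, samples)
    x1 <- rows$allele1; x2 <- rows$allele2
    x1[x1 == "0"] <- NA; x2[x2 == "0"] <- NA
    miss <- is.na(x1) | is.na(x2)
    a1[i[!miss], j] <- match(x1[!miss], alleles) - 1L
    a2[i[!miss], j] <- match(x2[!miss], alleles) - 1L
  }
  map <- marker_map(mk$marker, mk$chrom, as.integer(mk$pos), ref, alt)
  genotype_matrix(a1, a2, map, samples)
}

## ---------------------------------------------------------------------------
## Writing genotypes (deterministic text output, round-trip safe)

#' Write genotypes to a standard text format
#'
#' @param g a \code{GenotypeMatrix}.
#' @param path output path (for \code{plink_text}, the \code{.ped} path).
#' @param format one of \code{"vcf"}, \code{"plink_text"}, \code{"tsv"}.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "plink_text", "tsv")) {
  format <- match.arg(format)
  switch(format,
         vcf = write_genotypes_vcf(g, path),
         plink_text = write_genotypes_plink(g, path),
         tsv = write_genotypes_tsv(g, path))
  invisible(path)
}

write_genotypes_vcf <- function(g, path, haps = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  sep <- if (is.null(haps)) "/" else "|"
  a1 <- t(g$a1); a2 <- t(g$a2)   # markers x samples
  gt <- matrix(paste(ifelse(is.na(a1), ".", a1), ifelse(is.na(a2), ".", a2),
                     sep = sep), nrow = nrow(a1))
  lines <- paste(g$map$chrom, g$map$pos, g$map$id, g$map$ref, g$map$alt,
                 ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
}

#' Write phased haplotypes as a phased VCF
#' @param h a \code{HaplotypeMatrix}.
#' @param path output path.
#' @export
write_haplotypes_vcf <- function(h, path) {
  g <- as_genotypes(h)
  write_genotypes_vcf(g, path, haps = TRUE)
  invisible(path)
}

write_genotypes_plink <- function(g, ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path)) map_path <- paste0(ped_path, ".map")
  utils::write.table(
    data.frame(g$map$chrom, g$map$id, 0, g$map$pos),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  base <- function(mat) {
    out <- matrix("0", nrow(mat), ncol(mat))
    for (j in seq_len(ncol(mat))) {
      al <- marker_alleles(g$map, j)
      out[, j] <- ifelse(is.na(mat[, j]), "0", al[mat[, j] + 1L])
    }
    out
  }
  b1 <- base(g$a1); b2 <- base(g$a2)
  inter <- matrix("", nrow(b1), 2L * ncol(b1))
  inter[, seq(1L, ncol(inter), 2L)] <- b1
  inter[, seq(2L, ncol(inter), 2L)] <- b2
  ped <- cbind(unname(g$pop), g$samples, "0", "0", "0", "-9", inter)
  utils::write.table(ped, ped_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

write_genotypes_tsv <- function(g, path) {
  long <- expand.grid(si = seq_along(g$samples), mi = seq_len(nrow(g$map)))
  al <- function(mat) {
    vapply(seq_len(nrow(long)), function(k) {
      code <- mat[long$si[k], long$mi[k]]
      if (is.na(code)) "0" else marker_alleles(g$map, long$mi[k])[code + 1L]
    }, "")
  }
  out <- data.frame(sample = g$samples[long$si],
                    marker = g$map$id[long$mi],
                    chrom = g$map$chrom[long$mi],
                    pos = g$map$pos[long$mi],
                    allele1 = al(g$a1), allele2 = al(g$a2))
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
}

#' Subset a GenotypeMatrix
#' @param g a \code{GenotypeMatrix}.
#' @param samples sample ids or indices (default all).
#' @param markers marker ids or indices (default all).
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_along(g$samples) else {
    if (is.character(samples)) match(samples, g$samples) else samples
  }
  mi <- if (is.null(markers)) seq_len(nrow(g$map)) else {
    if (is.character(markers)) match(markers, g$map$id) else markers
  }
  if (anyNA(si) || anyNA(mi)) stop("unknown sample or marker", call. = FALSE)
  map <- g$map[mi, , drop = FALSE]
  class(map) <- c("MarkerMap", "data.frame")
  genotype_matrix(g$a1[si, mi, drop = FALSE], g$a2[si, mi, drop = FALSE],
                  map, g$samples[si], unname(g$pop[si]))
}

#' Subset a HaplotypeMatrix
#' @param h a \code{HaplotypeMatrix}.
#' @param haps haplotype ids or indices (default all).
#' @param markers marker ids or indices (default all).
#' @export
subset_haplotypes <- function(h, haps = NULL, markers = NULL) {
  hi <- if (is.null(haps)) seq_along(h$hap_ids) else {
    if (is.character(haps)) match(haps, h$hap_ids) else haps
  }
  mi <- if (is.null(markers)) seq_len(nrow(h$map)) else {
    if (is.character(markers)) match(markers, h$map$id) else markers
  }
  if (anyNA(hi) || anyNA(mi)) stop("unknown haplotype or marker",
                                   call. = FALSE)
  map <- h$map[mi, , drop = FALSE]
  class(map) <- c("MarkerMap", "data.frame")
  haplotype_matrix(h$haps[hi, mi, drop = FALSE], map, h$hap_ids[hi],
                   unname(h$sample_of[hi]), unname(h$pop[hi]))
}
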