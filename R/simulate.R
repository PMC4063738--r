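#' Introgression scenario
#'
#' Parameters of the synthetic introgression generator. The defaults encode
#' the study conditions the pipeline was built to detect: four demes carrying
#' a single donor-derived haplotype block (expected total length 750 kb)
#' around a focal locus at deme-specific donor-haplotype frequencies of
#' 0.31/0.20/0.20/0.02, in a low-diversity recipient population. Donor block
#' erosion is modeled directly: the two one-sided block lengths are
#' independent Exponential draws with mean \code{block_halflife}
#' (= \code{donor_block_target / 2}), the first-order expectation for a block
#' g generations after a single hybridization event.
#'
#' @param n_demes number of demes.
#' @param carrier_freq donor-haplotype frequency per deme.
#' @param n_diploids diploid sample size per deme.
#' @param chrom_length chromosome length, bp.
#' @param n_snps number of SNP markers (including the diagnostic SNP).
#' @param focal_pos position of the focal (diagnostic) SNP, bp.
#' @param donor_block_target expected total donor-block length, bp.
#' @param block_halflife expected one-sided block length, bp
#'   (default \code{donor_block_target / 2}).
#' @param recipient_maf_shape1,recipient_maf_shape2 Beta parameters of the
#'   per-site recipient allele-frequency distribution (low diversity).
#' @param donor_divergence fraction of SNPs at which the donor haplotype
#'   carries an allele absent from the recipient population.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return an \code{IntrogressionScenario} (list).
#' @export
introgression_scenario <- function(n_demes = 4L,
                                   carrier_freq = c(0.31, 0.20, 0.20, 0.02),
                                   n_diploids = rep(25L, 4L),
                                   chrom_length = 6e6,
                                   n_snps = 400L,
                                   focal_pos = 3e6,
                                   donor_block_target = 750000,
                                   block_halflife = donor_block_target / 2,
                                   recipient_maf_shape1 = 0.8,
                                   recipient_maf_shape2 = 4,
                                   donor_divergence = 0.5,
                                   seed = 1L) {
  stopifnot(length(carrier_freq) == n_demes,
            all(carrier_freq >= 0), all(carrier_freq <= 1),
            focal_pos >= 1, focal_pos <= chrom_length,
            n_snps >= 2L, donor_divergence >= 0, donor_divergence <= 1)
  if (length(n_diploids) == 1L) n_diploids <- rep(n_diploids, n_demes)
  structure(list(n_demes = as.integer(n_demes),
                 carrier_freq = carrier_freq,
                 n_diploids = as.integer(n_diploids),
                 chrom_length = chrom_length, n_snps = as.integer(n_snps),
                 focal_pos = focal_pos,
                 donor_block_target = donor_block_target,
                 block_halflife = block_halflife,
                 recipient_maf_shape1 = recipient_maf_shape1,
                 recipient_maf_shape2 = recipient_maf_shape2,
                 donor_divergence = donor_divergence,
                 seed = as.integer(seed)),
            class = "IntrogressionScenario")
}

#' Generate a synthetic introgression dataset
#'
#' Recipient haplotypes are drawn i.i.d. per site from the low-diversity
#' allele-frequency distribution. Each carrier haplotype receives the single
#' donor haplotype over an interval around \code{focal_pos} with independent
#' exponential one-sided lengths (mean \code{block_halflife}), truncated to
#' the chromosome. The diagnostic SNP at \code{focal_pos} is fixed-different
#' between donor and recipient. Diploids are formed by random pairing within
#' deme, honoring the target carrier frequency in expectation.
#'
#' @param s an \code{IntrogressionScenario}.
#' @return list with elements \code{haplotypes} (\code{HaplotypeMatrix}),
#'   \code{genotypes} (\code{GenotypeMatrix}), \code{map}
#'   (\code{MarkerMap}), \code{truth_labels} (\code{CarrierLabels} from the
#'   generating process), and \code{truth} (per-haplotype donor-block
#'   intervals, per-deme realized carrier frequencies, scenario and seed).
#' @export
generate_introgression_dataset <- function(s = introgression_scenario()) {
  stopifnot(inherits(s, "IntrogressionScenario"))
  rng <- local_rng(s$seed)

  pos <- sort(sample.int(s$chrom_length, s$n_snps - 1L))
  pos <- pos[pos != s$focal_pos]
  pos <- sort(c(pos, s$focal_pos))
  while (length(pos) < s$n_snps) {
    extra <- sample.int(s$chrom_length, s$n_snps - length(pos))
    pos <- sort(unique(c(pos, extra)))
  }
  n_snps <- length(pos)
  focal_idx <- match(s$focal_pos, pos)

  # recipient per-site allele-1 frequencies; donor haplotype
  q <- stats::rbeta(n_snps, s$recipient_maf_shape1, s$recipient_maf_shape2)
  divergent <- stats::runif(n_snps) < s$donor_divergence
  donor <- integer(n_snps)
  q[divergent] <- 0                       # allele 1 absent in recipients
  donor[divergent] <- 1L
  donor[!divergent] <- stats::rbinom(sum(!divergent), 1L, q[!divergent])
  divergent[focal_idx] <- TRUE            # diagnostic SNP fixed-different
  q[focal_idx] <- 0
  donor[focal_idx] <- 1L

  map <- marker_map(id = sprintf("snp%05d", seq_len(n_snps)),
                    chrom = rep("chr23", n_snps), pos = pos)
  map$id[focal_idx] <- "snp_diag"

  n_hap_total <- sum(2L * s$n_diploids)
  haps <- matrix(0L, n_hap_total, n_snps)
  hap_deme <- rep(seq_len(s$n_demes), times = 2L * s$n_diploids)
  is_carrier <- logical(n_hap_total)
  block <- matrix(NA_real_, n_hap_total, 2L,
                  dimnames = list(NULL, c("start", "end")))

  for (d in seq_len(s$n_demes)) {
    idx <- which(hap_deme == d)
    n_hap <- length(idx)
    f <- s$carrier_freq[d]
    if (f > 0 && f < 1 / n_hap) {
      warning(sprintf(
        "deme %d: target carrier frequency %.3f below 1/%d; realized frequency reported in truth",
        d, f, n_hap))
    }
    carrier <- stats::runif(n_hap) < f
    is_carrier[idx] <- carrier
    haps[idx, ] <- matrix(stats::rbinom(n_hap * n_snps, 1L, rep(q, each = n_hap)),
                          n_hap, n_snps)
    for (i in idx[carrier]) {
      left <- stats::rexp(1, rate = 1 / s$block_halflife)
      right <- stats::rexp(1, rate = 1 / s$block_halflife)
      lo <- max(1, s$focal_pos - left)
      hi <- min(s$chrom_length, s$focal_pos + right)
      inblock <- pos >= lo & pos <= hi
      haps[i, inblock] <- donor[inblock]
      block[i, ] <- c(lo, hi)
    }
  }

  # pair haplotypes into diploids within deme, random pairing
  hap_ids <- character(n_hap_total)
  sample_of <- character(n_hap_total)
  pop <- paste0("deme", hap_deme)
  samp_counter <- 0L
  ord <- integer(0)
  for (d in seq_len(s$n_demes)) {
    idx <- sample(which(hap_deme == d))
    ord <- c(ord, idx)
    for (k in seq_len(length(idx) / 2L)) {
      samp_counter <- samp_counter + 1L
      sid <- sprintf("d%d_s%03d", d, samp_counter)
      pair <- idx[c(2L * k - 1L, 2L * k)]
      sample_of[pair] <- sid
      hap_ids[pair] <- paste0(sid, c("_A", "_B"))
    }
  }
  h <- haplotype_matrix(haps[ord, , drop = FALSE], map, hap_ids[ord],
                        sample_of[ord], pop[ord])
  g <- as_genotypes(h)
  truth_labels <- classify_carriers(g, "snp_diag", 1L)

  realized <- vapply(seq_len(s$n_demes), function(d) {
    mean(is_carrier[hap_deme == d])
  }, 0)
  truth <- list(
    block_intervals = data.frame(hap_id = hap_ids[ord],
                                 start = block[ord, 1], end = block[ord, 2],
                                 stringsAsFactors = FALSE),
    carrier_class = truth_labels,
    realized_carrier_freq = realized,
    divergent_sites = map$id[divergent],
    scenario = s, seed = s$seed)
  list(haplotypes = h, genotypes = g, map = map,
       truth_labels = truth_labels, truth = truth)
}

#' Generate a structured alignment set
#'
#' Builds an alignment with an identical "native" haplotype group, an
#' identical "carrier" haplotype group diverged from it at
#' \code{round(native_carrier_divergence * length)} sites, one donor sequence
#' differing from the carrier consensus at exactly
#' \code{donor_carrier_diffs} sites, and further donor sequences mutated
#' freely at rate \code{donor_free_rate}.
#'
#' @param n_native,n_carrier,n_donor group sizes.
#' @param length alignment length, bp.
#' @param native_carrier_divergence p-distance between native and carrier
#'   haplotypes.
#' @param donor_carrier_diffs count of sites separating the first donor from
#'   the carrier haplotype.
#' @param donor_free_rate per-site mutation rate for the remaining donors.
#' @param seed integer seed.
#' @return a \code{SequenceAlignment}; group membership is recoverable from
#'   the name prefixes \code{native_}, \code{carrier_}, \code{donor_}.
#' @export
generate_alignment_set <- function(n_native = 7L, n_carrier = 7L,
                                   n_donor = 5L, length = 2253L,
                                   native_carrier_divergence = 0.051,
                                   donor_carrier_diffs = 5L,
                                   donor_free_rate = 0.03,
                                   seed = 1L) {
  stopifnot(native_carrier_divergence >= 0, native_carrier_divergence <= 1,
            length >= donor_carrier_diffs)
  n_div <- round(native_carrier_divergence * length)
  if (n_div + donor_carrier_diffs > length) {
    stop("site budget exceeded: divergence sites + donor diffs > length",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  bases <- c("A", "C", "G", "T")
  carrier <- sample(bases, length, replace = TRUE)
  div_sites <- sample.int(length, n_div)
  native <- carrier
  native[div_sites] <- vapply(carrier[div_sites], function(b) {
    sample(setdiff(bases, b), 1L)
  }, "")
  donor_sites <- sample(setdiff(seq_len(length), div_sites),
                        donor_carrier_diffs)
  donor1 <- carrier
  donor1[donor_sites] <- vapply(carrier[donor_sites], function(b) {
    sample(setdiff(bases, b), 1L)
  }, "")
  seqs <- c(
    stats::setNames(rep(paste(native, collapse = ""), n_native),
                    if (n_native) paste0("native_", seq_len(n_native))),
    stats::setNames(rep(paste(carrier, collapse = ""), n_carrier),
                    if (n_carrier) paste0("carrier_", seq_len(n_carrier))))
  if (n_donor >= 1L) {
    donors <- stats::setNames(paste(donor1, collapse = ""), "donor_1")
    if (n_donor > 1L) {
      for (k in 2:n_donor) {
        dk <- donor1
        mut <- which(stats::runif(length) < donor_free_rate)
        dk[mut] <- vapply(dk[mut], function(b) {
          sample(setdiff(bases, b), 1L)
        }, "")
        donors[paste0("donor_", k)] <- paste(dk, collapse = "")
      }
    }
    seqs <- c(seqs, donors)
  }
  sequence_alignment(seqs)
}

#' Append recombinant (mosaic) sequences to an alignment
#'
#' Each child switches among the parent sequences at the given breakpoints
#' (mosaic blocks are \code{[1, b1]}, \code{(b1, b2]}, ...). A positive
#' control for the Phi recombination test.
#'
#' @param parents a \code{SequenceAlignment} of at least 2 parents.
#' @param breakpoints strictly increasing positions within the alignment, or
#'   a list of such vectors (one child per element).
#' @param parent_order integer vector(s) of parent indices per mosaic block
#'   (recycled); default cycles 1, 2, 3, ...
#' @param child_names names for the children.
#' @return the alignment with children appended.
#' @export
generate_recombinant_alignment <- function(parents, breakpoints,
                                           parent_order = NULL,
                                           child_names = NULL) {
  stopifnot(inherits(parents, "SequenceAlignment"))
  if (n_sequences(parents) < 2L) stop("need at least 2 parents",
                                      call. = FALSE)
  if (!is.list(breakpoints)) breakpoints <- list(breakpoints)
  if (!is.null(parent_order) && !is.list(parent_order)) {
    parent_order <- list(parent_order)
  }
  if (is.null(child_names)) {
    child_names <- paste0("recomb_", seq_along(breakpoints))
  }
  pm <- alignment_matrix(parents)
  L <- parents$length
  kids <- character(length(breakpoints))
  for (ci in seq_along(breakpoints)) {
    bp <- breakpoints[[ci]]
    if (length(bp)) {
      if (any(diff(bp) <= 0)) stop("breakpoints must be strictly increasing",
                                   call. = FALSE)
      if (any(bp < 1 | bp >= L)) stop("breakpoint outside alignment",
                                      call. = FALSE)
    }
    bounds <- c(0L, as.integer(bp), L)
    n_blocks <- length(bounds) - 1L
    po <- if (is.null(parent_order)) {
      rep_len(seq_len(nrow(pm)), n_blocks)
    } else rep_len(parent_order[[ci]], n_blocks)
    child <- character(L)
    for (b in seq_len(n_blocks)) {
      seg <- (bounds[b] + 1L):bounds[b + 1L]
      child[seg] <- pm[po[b], seg]
    }
    kids[ci] <- paste(child, collapse = "")
  }
  sequence_alignment(c(parents$seqs, stats::setNames(kids, child_names)))
}

#' Generate a mosaic panel as a recombination positive control
#'
#' Draws divergent random parents and mosaic children with uniform random
#' breakpoints — the configuration in which a windowed homoplasy test must
#' reject clonality.
#'
#' @param n_parents,n_children panel sizes.
#' @param length alignment length, bp.
#' @param divergence expected pairwise parent divergence.
#' @param n_breakpoints breakpoints per child.
#' @param seed integer seed.
#' @return a \code{SequenceAlignment} of parents plus children.
#' @export
generate_mosaic_panel <- function(n_parents = 5L, n_children = 10L,
                                  length = 1000L, divergence = 0.2,
                                  n_breakpoints = 4L, seed = 1L) {
  rng <- local_rng(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  seqs <- character(n_parents)
  # pairwise divergence ~ 2 * rate * (1 - rate * 4/3 ...) ~= divergence
  rate <- divergence / 2 / (1 - divergence / 2 * 4 / 3)
  for (p in seq_len(n_parents)) {
    sp <- anc
    mut <- which(stats::runif(length) < rate)
    sp[mut] <- sample(bases, length(mut), replace = TRUE)
    seqs[p] <- paste(sp, collapse = "")
  }
  names(seqs) <- paste0("parent_", seq_len(n_parents))
  parents <- sequence_alignment(seqs)
  bps <- replicate(n_children,
                   sort(sample.int(length - 1L, n_breakpoints)),
                   simplify = FALSE)
  orders <- replicate(n_children,
                      sample.int(n_parents, n_breakpoints + 1L,
                                 replace = TRUE),
                      simplify = FALSE)
  generate_recombinant_alignment(parents, bps, orders,
                                 paste0("child_", seq_len(n_children)))
}

#' Synthetic stand-in for the sequenced DRB gene panel
#'
#' Builds, from seed alone, an alignment panel with the structure of the
#' sequenced MHC DRB study panel: (i) an ibex set of 7 + 7 sequences, each
#' group carrying one fixed haplotype, the two haplotypes differing at
#' \code{n_hap_diffs} of \code{length} sites; (ii) a donor goat sequence
#' differing from the carrier haplotype at exactly \code{donor_diffs} sites;
#' (iii) a goat panel of \code{n_goats} sequences with
#' \code{n_goat_informative} informative sites arranged in contiguous
#' recombination-style blocks of alternating sequence bipartitions, so the
#' panel carries a strong windowed-homoplasy recombination signal. This is a
#' synthetic emulation — the real panel's sequences are not redistributed
#' with the package — but every summary statistic computed from it
#' (identity, divergence, informative-site counts, Phi p-values) follows
#' from its construction.
#'
#' @param length alignment length in bp.
#' @param n_hap_diffs sites separating the two ibex haplotypes.
#' @param donor_diffs sites separating the donor goat from the carrier
#'   haplotype.
#' @param n_goats goat panel size.
#' @param n_goat_informative informative sites planted in the goat panel.
#' @param block_size informative sites per recombination block.
#' @param seed integer seed.
#' @return list with \code{ibex} (14-sequence \code{SequenceAlignment}),
#'   \code{ibex_with_donor} (the ibex panel plus the donor goat, named
#'   \code{donor_goat}), and \code{goats} (the goat panel).
#' @export
synthesize_drb_panel <- function(length = 2253L, n_hap_diffs = 116L,
                                 donor_diffs = 5L, n_goats = 5L,
                                 n_goat_informative = 64L, block_size = 8L,
                                 seed = 1L) {
  rng <- local_rng(seed)
  bases <- c("A", "C", "G", "T")

  carrier <- sample(bases, length, replace = TRUE)
  div_sites <- sample.int(length, n_hap_diffs)
  native <- carrier
  native[div_sites] <- vapply(carrier[div_sites], function(b) {
    sample(setdiff(bases, b), 1L)
  }, "")
  donor_sites <- sample(setdiff(seq_len(length), div_sites), donor_diffs)
  donor <- carrier
  donor[donor_sites] <- vapply(carrier[donor_sites], function(b) {
    sample(setdiff(bases, b), 1L)
  }, "")

  ibex_seqs <- c(
    stats::setNames(rep(paste(native, collapse = ""), 7L),
                    paste0("ibex_DRB1_", 1:7)),
    stats::setNames(rep(paste(carrier, collapse = ""), 7L),
                    paste0("ibex_DRB2_", 1:7)))
  ibex <- sequence_alignment(ibex_seqs)
  ibex_with_donor <- sequence_alignment(
    c(ibex_seqs, stats::setNames(paste(donor, collapse = ""), "donor_goat")))

  # goat panel: informative sites in contiguous blocks; each block carries
  # one 2-vs-3 bipartition; adjacent blocks use mutually incompatible
  # bipartitions (pairwise-intersecting minority pairs {1,k})
  goat_base <- sample(bases, length, replace = TRUE)
  gm <- matrix(rep(goat_base, each = n_goats), nrow = n_goats)
  spacing <- floor((length - 20L) / n_goat_informative)
  info_pos <- 10L + spacing * (seq_len(n_goat_informative) - 1L)
  minority_sets <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(1L, 5L))
  for (k in seq_len(n_goat_informative)) {
    blk <- ((k - 1L) %/% block_size) %% length(minority_sets) + 1L
    ref_b <- gm[1L, info_pos[k]]
    alt_b <- sample(setdiff(bases, ref_b), 1L)
    gm[minority_sets[[blk]], info_pos[k]] <- alt_b
  }
  goats <- sequence_alignment(stats::setNames(
    apply(gm, 1L, paste, collapse = ""), paste0("goat_", seq_len(n_goats))))

  list(ibex = ibex, ibex_with_donor = ibex_with_donor, goats = goats)
}

# seed the generator's private stream; the caller's stream is restored when
# the calling function exits
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}
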