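#' Diagnostic-marker concordance
#'
#' Cross-tabulates the per-sample copy number of a designated allele at two
#' markers over the samples typed at both. An allele pair whose copy
#' numbers agree in every sample is flagged diagnostic; for near-complete
#' pairs the mismatch count is reported. Works for biallelic SNPs and
#' multi-allelic (microsatellite-like) markers alike.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param marker_a,marker_b marker ids or indices.
#' @param allele_a,allele_b allele codes whose copy numbers are compared
#'   (default: every allele pair is scanned and the best-matching pair
#'   reported).
#' @return a \code{ConcordanceTable}: list with \code{joint} (copy-number
#'   cross-table), \code{concordance}, \code{n_mismatch}, \code{n_total},
#'   \code{allele_a}, \code{allele_b}, \code{diagnostic} flag, and
#'   \code{pairs} (per-allele-pair concordance scan).
#' @export
diagnostic_concordance <- function(g, marker_a, marker_b,
                                   allele_a = NULL, allele_b = NULL) {
  mi <- marker_index(g$map, marker_a); mj <- marker_index(g$map, marker_b)
  ok <- !is.na(g$a1[, mi]) & !is.na(g$a1[, mj])
  if (!any(ok)) stop("no sample typed at both markers", call. = FALSE)
  copies <- function(m, allele) {
    (g$a1[ok, m] == allele) + (g$a2[ok, m] == allele)
  }
  alleles_i <- seq_along(marker_alleles(g$map, mi)) - 1L
  alleles_j <- seq_along(marker_alleles(g$map, mj)) - 1L
  scan <- expand.grid(allele_a = alleles_i, allele_b = alleles_j)
  scan$concordance <- vapply(seq_len(nrow(scan)), function(k) {
    mean(copies(mi, scan$allele_a[k]) == copies(mj, scan$allele_b[k]))
  }, 0)
  if (is.null(allele_a) || is.null(allele_b)) {
    best <- which.max(scan$concordance)
    allele_a <- scan$allele_a[best]; allele_b <- scan$allele_b[best]
  }
  ca <- copies(mi, allele_a); cb <- copies(mj, allele_b)
  joint <- table(factor(ca, 0:2), factor(cb, 0:2),
                 dnn = c("copies_a", "copies_b"))
  conc <- mean(ca == cb)
  structure(list(joint = joint, concordance = conc,
                 n_mismatch = sum(ca != cb), n_total = sum(ok),
                 allele_a = allele_a, allele_b = allele_b,
                 diagnostic = conc == 1, pairs = scan),
            class = "ConcordanceTable")
}

#' @export
print.ConcordanceTable <- function(x, ...) {
  cat(sprintf(
    "Concordance (allele %s vs %s): %d/%d samples (%.4f)%s\n",
    x$allele_a, x$allele_b, x$n_total - x$n_mismatch, x$n_total,
    x$concordance, if (x$diagnostic) " [diagnostic]" else ""))
  invisible(x)
}

#' Run the full introgression-signature battery
#'
#' Chains the pipeline stages on one dataset: QC, carrier classification,
#' per-population LD with decay fits, EHH/iHH at the diagnostic SNP,
#' sliding-window He by carrier class, haplotype networks with
#' cluster-cohesion per chromosome section, and (when alignments are
#' supplied) divergence and the Phi recombination test. Stage failures are
#' recorded and independent stages continue. All artifacts are written
#' under \code{out_dir} together with a machine-readable JSON summary
#' carrying seeds, parameters and a config hash.
#'
#' @param config list (or path to a flat \code{key = value} file) with
#'   entries: \code{genotypes} (GenotypeMatrix) and/or \code{haplotypes}
#'   (HaplotypeMatrix), \code{diagnostic_marker}, \code{introgressed_allele}
#'   (default 1), optional \code{alignment} (SequenceAlignment), and
#'   optional analysis parameters (\code{window_bp}, \code{step_bp},
#'   \code{min_maf}, \code{marker_call_rate}, \code{sample_call_rate},
#'   \code{phi_window}, \code{n_perm}, \code{seed},
#'   \code{section_breaks}, \code{max_network_haps}).
#' @param out_dir output directory (created).
#' @return an \code{AnalysisReport} list (invisibly); \code{$exit_status}
#'   is 0 on success, 2 when a stage failed.
#' @export
run_full_analysis <- function(config, out_dir = tempfile("introsig_")) {
  if (is.character(config)) config <- read_flat_config(config)
  defaults <- list(introgressed_allele = 1L, window_bp = 500000,
                   step_bp = 100000, min_maf = 0.01,
                   marker_call_rate = 0.7, sample_call_rate = 0.9,
                   phi_window = 100, n_perm = 1000L, seed = 1L,
                   max_network_haps = 40L, density_bin_bp = 100000)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), parameters = cfg[!vapply(cfg, is.object_like, TRUE)],
                 seed = cfg$seed, out_dir = out_dir)
  failed <- character(0)
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      failed <<- c(failed, name)
      list(error = conditionMessage(e))
    })
    report$stages[[name]] <<- res
    res
  }

  g <- cfg$genotypes
  h <- cfg$haplotypes
  if (is.null(g) && !is.null(h)) g <- as_genotypes(h)
  if (is.null(g)) stop("config must provide genotypes or haplotypes",
                       call. = FALSE)

  qc <- run_stage("qc", function() {
    gq <- qc_genotypes(g, cfg$sample_call_rate, cfg$marker_call_rate,
                       cfg$min_maf, drop_obs_het_one = TRUE)
    log <- attr(gq, "qc_log")
    utils::write.table(log$marker_log,
                       file.path(out_dir, "qc_marker_log.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    list(n_samples = length(gq$samples), n_markers = nrow(gq$map),
         genotypes = gq)
  })
  gq <- if (!is.null(qc$genotypes)) qc$genotypes else g
  # keep the diagnostic marker even if QC would drop it (it is the anchor)
  if (!cfg$diagnostic_marker %in% gq$map$id &&
      cfg$diagnostic_marker %in% g$map$id) {
    keep <- sort(unique(c(match(gq$map$id, g$map$id),
                          match(cfg$diagnostic_marker, g$map$id))))
    gq <- subset_genotypes(g, samples = match(gq$samples, g$samples),
                           markers = keep)
  }

  labels <- run_stage("carriers", function() {
    cl <- classify_carriers(gq, cfg$diagnostic_marker,
                            cfg$introgressed_allele)
    utils::write.table(data.frame(sample = names(cl),
                                  class = as.character(cl)),
                       file.path(out_dir, "carrier_classes.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    cl
  })

  chrom <- gq$map$chrom[marker_index(gq$map, cfg$diagnostic_marker)]
  region <- list(chrom, min(gq$map$pos[gq$map$chrom == chrom]),
                 max(gq$map$pos[gq$map$chrom == chrom]))

  ld_res <- run_stage("ld", function() {
    per_pop <- list()
    for (p in unique(unname(gq$pop))) {
      xs <- if (!is.null(h)) {
        subset_haplotypes(h, haps = which(unname(h$pop) == p))
      } else subset_genotypes(gq, samples = which(unname(gq$pop) == p))
      res <- tryCatch(ld_matrix(xs), error = function(e) NULL)
      if (is.null(res) || !nrow(res)) next
      write_ld_pairs(res, file.path(out_dir, paste0("ld_", p, ".tsv")))
      n_hap <- if (!is.null(h)) sum(unname(h$pop) == p) else
        2L * sum(unname(gq$pop) == p)
      fit <- tryCatch(ld_decay_fit(res, n_hap), error = function(e) NULL)
      classes <- ld_block_classes(res, if (!is.null(h)) h$map else gq$map)
      per_pop[[p]] <- list(n_pairs = nrow(res),
                           rho = if (is.null(fit)) NA_real_ else fit$rho,
                           strong_span = classes$spans[["strong"]],
                           class_counts = as.list(classes$counts))
    }
    per_pop
  })

  ehh_res <- run_stage("ehh", function() {
    if (is.null(h)) return(list(skipped = "no phased haplotypes provided"))
    out <- list()
    for (al in c(cfg$introgressed_allele, 1L - cfg$introgressed_allele)) {
      e <- ehh_curve(h, cfg$diagnostic_marker, al)
      key <- if (al == cfg$introgressed_allele) "introgressed" else "native"
      if (isTRUE(e$computable)) {
        write_ehh_curve(e, file.path(out_dir, paste0("ehh_", key, ".tsv")))
      }
      out[[key]] <- list(computable = isTRUE(e$computable),
                         n_carriers = e$n_carriers,
                         ihh_total = e$ihh_total)
    }
    out
  })

  he_res <- run_stage("windows", function() {
    grp <- parse_groups(gq, labels)
    grp <- grp[setdiff(names(grp), "unknown")]
    track <- sliding_he(gq, region, cfg$window_bp, cfg$step_bp, grp)
    write_window_track(track, file.path(out_dir, "sliding_he.tsv"))
    dens <- snp_density(gq$map, region, cfg$density_bin_bp, cfg$min_maf,
                        gq, grp)
    write_window_track(dens, file.path(out_dir, "snp_density.tsv"))
    list(he_track = track, density = dens)
  })

  net_res <- run_stage("networks", function() {
    if (is.null(h)) return(list(skipped = "no phased haplotypes provided"))
    m <- nrow(h$map)
    breaks <- cfg$section_breaks
    if (is.null(breaks)) {
      breaks <- round(stats::quantile(seq_len(m), c(1 / 3, 2 / 3)))
    }
    bounds <- unique(c(0L, as.integer(breaks), m))
    out <- list()
    for (s in seq_len(length(bounds) - 1L)) {
      mi <- (bounds[s] + 1L):bounds[s + 1L]
      hs <- subset_haplotypes(h, markers = mi)
      # cap the network at the most frequent distinct haplotypes
      key <- apply(hs$haps, 1L, paste, collapse = "")
      freq <- sort(table(key), decreasing = TRUE)
      use <- match(names(freq)[seq_len(min(length(freq),
                                           cfg$max_network_haps))], key)
      has_diag <- cfg$diagnostic_marker %in% hs$map$id
      dd <- haplotype_distances(subset_haplotypes(hs, haps = use))
      coh <- tryCatch(
        cluster_cohesion(
          dd, h$haps[use, marker_index(h$map, cfg$diagnostic_marker)] ==
            cfg$introgressed_allele,
          seed = cfg$seed),
        error = function(e) list(score = NA_real_, p_value = NA_real_))
      ssys <- tryCatch(neighbornet(dd), error = function(e) NULL)
      if (!is.null(ssys)) {
        write_splits_nexus(ssys, file.path(out_dir,
                                           sprintf("network_section%d.nex", s)))
      }
      out[[sprintf("section%d", s)]] <- list(
        markers = range(h$map$pos[mi]), n_haps = length(use),
        contains_diagnostic = has_diag,
        cohesion = coh$score, cohesion_p = coh$p_value)
    }
    out
  })

  aln_res <- run_stage("alignment", function() {
    if (is.null(cfg$alignment)) return(list(skipped = "no alignment provided"))
    aln <- cfg$alignment
    dm <- distance_matrix(aln)
    write_distance_matrix(dm, file.path(out_dir, "alignment_pdist.tsv"))
    phi <- phi_permutation_test(aln, cfg$phi_window, cfg$n_perm, cfg$seed)
    write_phi_result(phi, file.path(out_dir, "phi.json"))
    list(mean_pdist = mean(dm$d[upper.tri(dm$d)]),
         phi_p = phi$p_value, n_informative = phi$n_informative)
  })

  report$failed_stages <- failed
  report$exit_status <- if (length(failed)) 2L else 0L
  report$provenance <- list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("introsig")),
    timestamp = NA)  # deterministic output: no wall-clock in the summary
  summary <- report
  summary$out_dir <- NULL                 # path varies run to run
  summary$stages$qc$genotypes <- NULL
  summary$stages$carriers <- table(as.character(labels))
  summary$stages$windows <- NULL
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, na = "null",
                       dataframe = "rows", force = TRUE)
  class(report) <- "AnalysisReport"
  invisible(report)
}

is.object_like <- function(x) {
  is.list(x) || inherits(x, c("GenotypeMatrix", "HaplotypeMatrix",
                              "SequenceAlignment")) || is.environment(x)
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport:", length(x$stages), "stages;",
      if (length(x$failed_stages)) paste("FAILED:",
                                         paste(x$failed_stages,
                                               collapse = ", "))
      else "all stages completed", "\n")
  invisible(x)
}

# flat key = value config files; values parsed as numbers when possible
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("bad config line: ", lines[bad][1], call. = FALSE)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1L))
}

config_hash <- function(cfg) {
  flat <- cfg[order(names(cfg))]
  flat <- flat[!vapply(flat, is.object_like, TRUE)]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(flat), vapply(flat, function(x) {
    paste(format(x, digits = 12), collapse = ",")
  }, ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}
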