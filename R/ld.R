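#' Pairwise r-squared from phased haplotypes
#'
#' Direct haplotype counting: \code{D = p_AB - p_A p_B},
#' \code{r2 = D^2 / (p_A q_A p_B q_B)}. Both markers must be biallelic and
#' polymorphic among the given haplotypes.
#'
#' @param h a \code{HaplotypeMatrix}.
#' @param i,j marker ids or indices.
#' @return an \code{LDResult} row (data.frame): marker ids, distance (bp),
#'   \code{r2}, \code{D}, \code{mode = "phased_count"}.
#' @export
haplotype_r2 <- function(h, i, j) {
  mi <- marker_index(h$map, i); mj <- marker_index(h$map, j)
  x <- h$haps[, mi]; y <- h$haps[, mj]
  pA <- mean(x == 1L); pB <- mean(y == 1L)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("monomorphic marker: LD undefined", call. = FALSE)
  }
  pAB <- mean(x == 1L & y == 1L)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  ld_row(h$map, mi, mj, r2, D, "phased_count")
}

marker_index <- function(map, i) {
  if (is.character(i)) {
    k <- match(i, map$id)
    if (is.na(k)) stop("unknown marker: ", i, call. = FALSE)
    k
  } else as.integer(i)
}

ld_row <- function(map, mi, mj, r2, D, mode, converged = TRUE) {
  data.frame(marker_i = map$id[mi], marker_j = map$id[mj],
             dist_bp = abs(map$pos[mj] - map$pos[mi]),
             r2 = r2, D = D, mode = mode, converged = converged,
             stringsAsFactors = FALSE)
}

#' Pairwise r-squared from unphased genotypes via EM
#'
#' Maximum-likelihood two-locus haplotype frequencies under
#' Hardy-Weinberg random pairing, estimated by EM (double heterozygotes are
#' phase-ambiguous and split between cis and trans configurations each
#' iteration); r2 and D then follow as in the phased case. With no double
#' heterozygotes the EM fixed point equals direct counting.
#'
#' @param g a \code{GenotypeMatrix}.
#' @param i,j marker ids or indices.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return an \code{LDResult} row with \code{mode = "em_genotype"}.
#' @export
genotype_r2_em <- function(g, i, j, tol = 1e-10, max_iter = 1000L) {
  mi <- marker_index(g$map, i); mj <- marker_index(g$map, j)
  gx <- g$a1[, mi] + g$a2[, mi]
  gy <- g$a1[, mj] + g$a2[, mj]
  keep <- !is.na(gx) & !is.na(gy)
  gx <- gx[keep]; gy <- gy[keep]
  n <- length(gx)
  if (n == 0L) stop("no samples called at both markers", call. = FALSE)
  pA <- mean(gx) / 2; pB <- mean(gy) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("monomorphic marker: LD undefined", call. = FALSE)
  }
  # haplotype freqs (h00, h01, h10, h11); init at linkage equilibrium
  hf <- c((1 - pA) * (1 - pB), (1 - pA) * pB, pA * (1 - pB), pA * pB)
  dh <- gx == 1L & gy == 1L           # phase-ambiguous double heterozygotes
  n_dh <- sum(dh)
  # haplotype counts from phase-unambiguous genotypes (2 per sample)
  base_counts <- c(0, 0, 0, 0)
  for (s in seq_len(n)) {
    if (dh[s]) next
    x1 <- if (gx[s] == 2L) c(1L, 1L) else if (gx[s] == 0L) c(0L, 0L)
          else c(0L, 1L)
    y1 <- if (gy[s] == 2L) c(1L, 1L) else if (gy[s] == 0L) c(0L, 0L)
          else c(0L, 1L)
    base_counts <- base_counts + tabulate(2L * x1 + y1 + 1L, 4L)
  }
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E step: split double hets between cis (00/11) and trans (01/10)
    p_cis <- hf[1] * hf[4]
    p_trans <- hf[2] * hf[3]
    w <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    counts <- base_counts + n_dh * c(w, 1 - w, 1 - w, w)
    hf <- counts / sum(counts)
    ll <- loglik_2locus(hf, base_counts, n_dh)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  pA <- hf[3] + hf[4]; pB <- hf[2] + hf[4]
  D <- hf[4] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  ld_row(g$map, mi, mj, r2, D, "em_genotype", converged)
}

loglik_2locus <- function(hf, base_counts, n_dh) {
  lh <- ifelse(hf > 0, log(hf), -745)
  sum(base_counts * lh) +
    n_dh * log(max(2 * (hf[1] * hf[4] + hf[2] * hf[3]), 1e-300))
}

#' All pairwise LD within a distance cap
#'
#' Computes r2 for all marker pairs (optionally restricted to a subset and a
#' maximum pairwise distance). Phased input uses haplotype counting
#' (vectorized); genotype input uses the EM estimator per pair. Monomorphic
#' markers are skipped.
#'
#' @param x a \code{HaplotypeMatrix} or \code{GenotypeMatrix}.
#' @param markers optional marker ids/indices (must be position-sorted).
#' @param max_distance maximum pairwise distance in bp (Inf = all pairs).
#' @return data.frame of \code{LDResult} rows ordered for heatmap export.
#' @export
ld_matrix <- function(x, markers = NULL, max_distance = Inf) {
  map <- x$map
  mi <- if (is.null(markers)) seq_len(nrow(map)) else {
    vapply(markers, marker_index, 1L, map = map)
  }
  if (any(diff(map$pos[mi]) < 0)) {
    stop("markers must be sorted by position", call. = FALSE)
  }
  if (inherits(x, "HaplotypeMatrix")) {
    H <- x$haps[, mi, drop = FALSE]
    p <- colMeans(H == 1L)
    poly <- p > 0 & p < 1
    keep <- mi[poly]
    H <- H[, poly, drop = FALSE]; p <- p[poly]
    nk <- length(keep)
    out <- list()
    if (nk >= 2L) {
      PAB <- crossprod(H == 1L) / nrow(H)
      Dm <- PAB - outer(p, p)
      denom <- outer(p * (1 - p), p * (1 - p))
      R2 <- Dm^2 / denom
      ut <- which(upper.tri(R2), arr.ind = TRUE)
      a <- ut[, 1]; b <- ut[, 2]
      dist <- abs(map$pos[keep[b]] - map$pos[keep[a]])
      sel <- dist <= max_distance
      res <- data.frame(marker_i = map$id[keep[a[sel]]],
                        marker_j = map$id[keep[b[sel]]],
                        dist_bp = dist[sel],
                        r2 = R2[ut[sel, , drop = FALSE]],
                        D = Dm[ut[sel, , drop = FALSE]],
                        mode = "phased_count", converged = TRUE,
                        stringsAsFactors = FALSE)
      res <- res[order(match(res$marker_i, map$id),
                       match(res$marker_j, map$id)), ]
      rownames(res) <- NULL
      return(res)
    }
  } else if (inherits(x, "GenotypeMatrix")) {
    maf <- marker_maf(x)[mi]
    keep <- mi[!is.na(maf) & maf > 0]
    nk <- length(keep)
    out <- list()
    if (nk >= 2L) {
      for (a in seq_len(nk - 1L)) {
        for (b in (a + 1L):nk) {
          dist <- abs(map$pos[keep[b]] - map$pos[keep[a]])
          if (dist > max_distance) next
          out[[length(out) + 1L]] <- genotype_r2_em(x, keep[a], keep[b])
        }
      }
    }
  } else stop("x must be a HaplotypeMatrix or GenotypeMatrix", call. = FALSE)
  if (!length(out)) {
    return(data.frame(marker_i = character(), marker_j = character(),
                      dist_bp = numeric(), r2 = numeric(), D = numeric(),
                      mode = character(), converged = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify LD pairs into strength classes and measure spans
#'
#' Default classes follow the conventional cutoffs: strong r2 > 0.8,
#' moderate 0.5 < r2 <= 0.8, weak 0.2 < r2 <= 0.5 (half-open intervals
#' (lo, hi]). For each class the maximal genomic span is the longest
#' contiguous run obtained by merging the [pos_i, pos_j] intervals of that
#' class's pairs.
#'
#' @param results an \code{ld_matrix} result.
#' @param map the \code{MarkerMap} the results refer to.
#' @param classes data.frame with columns \code{name}, \code{lo}, \code{hi};
#'   intervals must be disjoint.
#' @return list with \code{counts} (per class), \code{spans} (per-class
#'   maximal merged span in bp) and \code{table} (per-chromosome class
#'   counts).
#' @export
ld_block_classes <- function(results, map,
                             classes = data.frame(
                               name = c("strong", "moderate", "weak"),
                               lo = c(0.8, 0.5, 0.2),
                               hi = c(1.0, 0.8, 0.5))) {
  o <- order(classes$lo)
  cl <- classes[o, ]
  if (any(cl$lo >= cl$hi)) stop("classes must have lo < hi", call. = FALSE)
  if (nrow(cl) > 1L && any(cl$hi[-nrow(cl)] > cl$lo[-1] + 1e-12)) {
    stop("classes must be disjoint", call. = FALSE)
  }
  counts <- stats::setNames(integer(nrow(classes)), classes$name)
  spans <- stats::setNames(numeric(nrow(classes)), classes$name)
  chrom_tab <- NULL
  if (nrow(results)) {
    pos_i <- map$pos[match(results$marker_i, map$id)]
    pos_j <- map$pos[match(results$marker_j, map$id)]
    chrom <- map$chrom[match(results$marker_i, map$id)]
    for (k in seq_len(nrow(classes))) {
      incl <- results$r2 > classes$lo[k] & results$r2 <= classes$hi[k]
      counts[k] <- sum(incl)
      spans[k] <- max_merged_span(pmin(pos_i, pos_j)[incl],
                                  pmax(pos_i, pos_j)[incl])
      tab <- table(chrom[incl])
      row <- stats::setNames(rep(0L, length(unique(chrom))), unique(chrom))
      row[names(tab)] <- as.integer(tab)
      chrom_tab <- rbind(chrom_tab, row)
    }
    rownames(chrom_tab) <- classes$name
  }
  list(counts = counts, spans = spans, table = chrom_tab)
}

# longest contiguous run covered by the union of intervals [lo, hi]
max_merged_span <- function(lo, hi) {
  if (!length(lo)) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  best <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[k])
    } else {
      best <- max(best, cur_hi - cur_lo)
      cur_lo <- lo[k]; cur_hi <- hi[k]
    }
  }
  max(best, cur_hi - cur_lo)
}

#' Expected r-squared under drift-recombination balance
#'
#' The sample-size-corrected expectation of r2 at population recombination
#' intensity \code{C = rho * d} for \code{n} sampled haplotypes:
#' \deqn{E[r^2] = \frac{10+C}{(2+C)(11+C)}
#'   \left[1 + \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right]}
#' with limits \eqn{(10/22)(1 + 18/(11n))} as \eqn{C \to 0} and \eqn{1/n} as
#' \eqn{C \to \infty}.
#'
#' @param C non-negative recombination intensity \code{rho * distance}.
#' @param n number of haplotypes.
#' @export
hill_expected_r2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD decay curve and estimate rho = 4Ner
#'
#' Ordinary (unweighted) least squares of observed pairwise r2 against the
#' \code{\link{hill_expected_r2}} curve with \code{C = rho * distance},
#' rho constrained non-negative; rho is initialized at 2/median(distance)
#' and optimized with a bounded quasi-Newton step. Steeper decay (larger
#' rho) means shorter LD blocks.
#'
#' @param results an \code{ld_matrix} result (columns \code{dist_bp},
#'   \code{r2}).
#' @param n_haplotypes number of haplotypes behind the r2 estimates.
#' @return a \code{DecayFit}: list with \code{rho} (per bp), \code{n},
#'   \code{rss}, \code{converged}, \code{n_pairs}.
#' @export
ld_decay_fit <- function(results, n_haplotypes) {
  d <- results$dist_bp; r2 <- results$r2
  keep <- is.finite(d) & is.finite(r2) & d > 0
  d <- d[keep]; r2 <- r2[keep]
  if (length(unique(d)) < 3L) {
    stop("need at least 3 distinct distances", call. = FALSE)
  }
  if (n_haplotypes < 4) stop("need n >= 4 haplotypes", call. = FALSE)
  rss <- function(log_rho) {
    sum((r2 - hill_expected_r2(exp(log_rho) * d, n_haplotypes))^2)
  }
  init <- log(2 / stats::median(d))
  fit <- stats::nlminb(init, rss, lower = init - 25, upper = init + 25)
  # polish across a wide bracket in case the surface is flat near init
  grid <- init + seq(-12, 12, by = 1)
  g_best <- grid[which.min(vapply(grid, rss, 0))]
  if (rss(g_best) < fit$objective) {
    fit <- stats::nlminb(g_best, rss, lower = g_best - 5, upper = g_best + 5)
  }
  structure(list(rho = exp(fit$par), n = n_haplotypes, rss = fit$objective,
                 converged = fit$convergence == 0,
                 n_pairs = length(d)),
            class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  cat(sprintf("LD decay fit: rho = %.3g per bp (n = %d, %d pairs, rss = %.4g%s)\n",
              x$rho, x$n, x$n_pairs, x$rss,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' VIF-based marker pruning
#'
#' Sliding-window pruning at linkage equilibrium: within each window of
#' \code{window_snps} markers (advancing by \code{step_snps}), markers whose
#' variance inflation factor \code{VIF = 1/(1 - R^2)} — R2 being the
#' multiple correlation of the marker regressed on the other retained
#' markers in the window — exceeds \code{vif_threshold} are dropped.
#' The sweep is deterministic, left to right. A marker whose regression is
#' singular is treated as fully predicted and dropped.
#'
#' @param x a \code{HaplotypeMatrix} or \code{GenotypeMatrix} (dosages).
#' @param window_snps window size in markers (>= 2).
#' @param step_snps step in markers.
#' @param vif_threshold VIF above which a marker is dropped (threshold 2
#'   equals an R2 > 0.5 rule).
#' @return character vector of retained marker ids.
#' @export
vif_prune <- function(x, window_snps = 50L, step_snps = 5L,
                      vif_threshold = 2) {
  stopifnot(window_snps >= 2L, step_snps >= 1L)
  X <- if (inherits(x, "HaplotypeMatrix")) x$haps else dosage(x)
  map <- x$map
  m <- ncol(X)
  retained <- rep(TRUE, m)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  retained[is.na(sds) | sds == 0] <- FALSE   # monomorphic: nothing to prune on
  start <- 1L
  repeat {
    end <- min(start + window_snps - 1L, m)
    w <- which(retained[start:end]) + start - 1L
    for (i in w) {
      others <- setdiff(which(retained[start:end]) + start - 1L, i)
      if (!length(others)) next
      r2 <- multiple_r2(X[, i], X[, others, drop = FALSE])
      vif <- if (is.na(r2)) Inf else if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
      if (vif > vif_threshold) retained[i] <- FALSE
    }
    if (end >= m) break
    start <- start + step_snps
  }
  map$id[retained]
}

# multiple correlation R^2 of y on columns of Z (complete cases)
multiple_r2 <- function(y, Z) {
  cc <- stats::complete.cases(y, Z)
  y <- y[cc]; Z <- Z[cc, , drop = FALSE]
  if (length(y) < 3L || stats::sd(y) == 0) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, Z), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Write LD pairs as TSV
#' @param results \code{ld_matrix} output.
#' @param path output path.
#' @export
write_ld_pairs <- function(results, path) {
  utils::write.table(results, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Export an ordered r2 matrix for heatmap rendering
#' @param results \code{ld_matrix} output.
#' @param map the corresponding \code{MarkerMap}.
#' @param path output path.
#' @export
write_ld_heatmap_matrix <- function(results, map, path) {
  ids <- map$id[map$id %in% c(results$marker_i, results$marker_j)]
  M <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(M) <- 1
  ii <- match(results$marker_i, ids); jj <- match(results$marker_j, ids)
  M[cbind(ii, jj)] <- results$r2
  M[cbind(jj, ii)] <- results$r2
  utils::write.table(M, path, quote = FALSE, sep = "\t", col.names = NA)
  invisible(path)
}
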