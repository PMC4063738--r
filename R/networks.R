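#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a p-distance matrix: repeated Q-matrix
#' minimization with the standard branch-length formulas. Ties in Q are
#' broken deterministically by the lexicographically smallest active-node
#' index pair. Negative branch-length estimates are clamped to zero; the
#' total clamped amount is recorded in \code{attr(, "clamped")}.
#'
#' @param d a \code{DistanceMatrix} (or symmetric matrix).
#' @return an unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(d) {
  if (!inherits(d, "DistanceMatrix")) d <- as_distance_matrix(d)
  D <- d$d
  if (!all(is.finite(D))) stop("non-finite distances", call. = FALSE)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labels <- d$taxa
  # node representation: newick fragments grown bottom-up
  nwk <- quote_labels(labels)
  clamped <- 0
  active <- seq_len(n)
  while (length(active) > 3L) {
    r <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    best <- arg_min_pair(Q)
    i <- best[1]; j <- best[2]
    li <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { clamped <- clamped - li; li <- 0 }
    if (lj < 0) { clamped <- clamped - lj; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    new_d <- (D[ai, ] + D[aj, ] - D[ai, aj]) / 2
    D <- rbind(cbind(D, new_d), c(new_d, 0))
    k <- nrow(D)
    nwk <- c(nwk, sprintf("(%s:%.10g,%s:%.10g)", nwk[ai], li, nwk[aj], lj))
    active <- c(setdiff(active, c(ai, aj)), k)
  }
  a <- active
  l1 <- (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]]) / 2
  l2 <- D[a[1], a[2]] - l1
  l3 <- D[a[1], a[3]] - l1
  ls <- c(l1, l2, l3)
  clamped <- clamped + sum(-pmin(ls, 0))
  ls <- pmax(ls, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[a[1]], ls[1], nwk[a[2]], ls[2], nwk[a[3]], ls[3])
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped") <- clamped
  tree
}

quote_labels <- function(x) gsub("[ ():,;]", "_", x)

# index pair of the minimum of a symmetric matrix, smallest (i, j) on ties
arg_min_pair <- function(Q) {
  m <- min(Q[upper.tri(Q)])
  idx <- which(Q <= m + 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  idx[1, ]
}

#' NeighborNet circular split network
#'
#' Two phases. (1) Agglomeration: clusters of one or two active nodes are
#' merged by the neighbor-joining criterion on cluster-averaged distances; a
#' second, node-level criterion chooses which chain ends to link, and each
#' three-node chain is immediately reduced to two nodes with the standard
#' (2/3, 1/3) distance updates. Backtracking the merges yields a circular
#' ordering of the taxa. Ties break at the smallest index pair. (2) Split
#' weights: all n(n-1)/2 splits contiguous in the circular ordering are fit
#' to the input distances by non-negative least squares (active-set method);
#' splits with weight below \code{tol} are dropped.
#'
#' @param d a \code{DistanceMatrix} (or symmetric matrix), >= 4 taxa.
#' @param tol weight threshold below which splits are dropped.
#' @return a \code{SplitSystem}: list with \code{order} (circular taxon
#'   ordering), \code{splits} (list of integer taxon-index sets),
#'   \code{weights}, \code{taxa}, \code{residual_norm}.
#' @export
neighbornet <- function(d, tol = 1e-9) {
  if (!inherits(d, "DistanceMatrix")) d <- as_distance_matrix(d)
  n <- length(d$taxa)
  if (n < 4L) stop("need at least 4 taxa", call. = FALSE)
  ord <- neighbornet_order(d$d)
  fit <- circular_split_weights(d$d, ord, tol)
  structure(list(order = ord, splits = fit$splits, weights = fit$weights,
                 taxa = d$taxa, residual_norm = fit$resnorm),
            class = "SplitSystem")
}

#' @export
print.SplitSystem <- function(x, ...) {
  cat("SplitSystem:", length(x$taxa), "taxa,", length(x$splits),
      "splits with positive weight\n")
  invisible(x)
}

# Agglomerative circular-ordering phase. Nodes live in a growing working
# distance matrix; clusters hold 1 or 2 active node slots; `ord` tracks the
# full taxon chain each cluster represents.
neighbornet_order <- function(d0) {
  d <- d0
  n <- nrow(d)
  CL <- as.list(seq_len(n))     # active node slots per cluster
  ord <- as.list(seq_len(n))    # taxon chains per cluster
  repeat {
    l <- length(CL)
    if (l <= 1L) break
    DM <- cluster_dist(d, CL)
    if (l > 2L) {
      r <- rowSums(DM) / (l - 2)
      Q <- DM - outer(r, r, "+")
      diag(Q) <- Inf
      sel <- arg_min_pair_full(Q)
    } else sel <- c(1L, 2L)
    e1 <- sel[1]; e2 <- sel[2]
    n1 <- length(CL[[e1]]); n2 <- length(CL[[e2]])
    if (n1 == 1L && n2 == 1L) {
      CL[[e1]] <- c(CL[[e1]], CL[[e2]])
      ord[[e1]] <- c(ord[[e1]], ord[[e2]])
      CL[[e2]] <- NULL; ord[[e2]] <- NULL
      next
    }
    # node-level selection among the chain ends
    x <- c(CL[[e1]], CL[[e2]])
    others <- CL[-c(e1, e2)]
    rx <- node_r(d, x, others)
    ltmp <- length(x) + length(others)
    if (ltmp > 2L) rx <- rx / (ltmp - 2)
    Dn <- d[x, x, drop = FALSE] - outer(rx, rx, "+")
    blk <- Dn[seq_len(n1), n1 + seq_len(n2), drop = FALSE]
    w <- which(blk == min(blk), arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    bi <- w[1, 1]; bj <- w[1, 2]
    c1 <- CL[[e1]]; c2 <- CL[[e2]]; o1 <- ord[[e1]]; o2 <- ord[[e2]]
    if (n1 == 2L && n2 == 1L) {
      if (bi == 2L) {           # chain c1[1]-c1[2]-c2
        d <- nn_reduce(d, c1[1], c1[2], c2[1])
        CL[[e1]] <- c(c1[1], c2[1]); ord[[e1]] <- c(o1, o2)
      } else {                  # chain c2-c1[1]-c1[2]
        d <- nn_reduce(d, c2[1], c1[1], c1[2])
        CL[[e1]] <- c(c2[1], c1[2]); ord[[e1]] <- c(o2, o1)
      }
    } else if (n1 == 1L && n2 == 2L) {
      if (bj == 1L) {           # chain c1-c2[1]-c2[2]
        d <- nn_reduce(d, c1[1], c2[1], c2[2])
        CL[[e1]] <- c(c1[1], c2[2]); ord[[e1]] <- c(o1, o2)
      } else {                  # chain c2[1]-c2[2]-c1
        d <- nn_reduce(d, c2[1], c2[2], c1[1])
        CL[[e1]] <- c(c2[1], c1[1]); ord[[e1]] <- c(o2, o1)
      }
    } else {                    # 2 and 2
      if (bi == 1L && bj == 1L) {        # x2-x1-y1-y2
        d <- nn_reduce(d, c1[2], c1[1], c2[1])
        d <- nn_reduce(d, c1[2], c2[1], c2[2])
        CL[[e1]] <- c(c1[2], c2[2]); ord[[e1]] <- c(rev(o1), o2)
      } else if (bi == 2L && bj == 1L) { # x1-x2-y1-y2
        d <- nn_reduce(d, c1[1], c1[2], c2[1])
        d <- nn_reduce(d, c1[1], c2[1], c2[2])
        CL[[e1]] <- c(c1[1], c2[2]); ord[[e1]] <- c(o1, o2)
      } else if (bi == 1L && bj == 2L) { # x2-x1-y2-y1
        d <- nn_reduce(d, c1[2], c1[1], c2[2])
        d <- nn_reduce(d, c1[2], c2[2], c2[1])
        CL[[e1]] <- c(c1[2], c2[1]); ord[[e1]] <- c(rev(o1), rev(o2))
      } else {                           # x1-x2-y2-y1
        d <- nn_reduce(d, c1[1], c1[2], c2[2])
        d <- nn_reduce(d, c1[1], c2[2], c2[1])
        CL[[e1]] <- c(c1[1], c2[1]); ord[[e1]] <- c(o1, rev(o2))
      }
    }
    CL[[e2]] <- NULL; ord[[e2]] <- NULL
  }
  ord[[1]]
}

cluster_dist <- function(d, CL) {
  l <- length(CL)
  DM <- matrix(0, l, l)
  for (i in seq_len(l - 1L)) {
    for (j in (i + 1L):l) {
      DM[i, j] <- DM[j, i] <- mean(d[CL[[i]], CL[[j]]])
    }
  }
  DM
}

# per-node row sums mixing node-to-node distances within x and mean
# node-to-cluster distances to the remaining clusters
node_r <- function(d, x, others) {
  vapply(seq_along(x), function(i) {
    s <- sum(d[x[i], x[-i]])
    for (cl in others) s <- s + mean(d[x[i], cl])
    s
  }, 0)
}

# replace the 3-chain (x, y, z) by two nodes stored in the x and z slots
nn_reduce <- function(d, x, y, z) {
  u <- 2 / 3 * d[x, ] + d[y, ] / 3
  v <- 2 / 3 * d[z, ] + d[y, ] / 3
  uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
  d[x, ] <- u; d[, x] <- u
  d[z, ] <- v; d[, z] <- v
  d[y, ] <- 0; d[, y] <- 0
  d[x, z] <- d[z, x] <- uv
  d[x, x] <- d[z, z] <- 0
  d
}

arg_min_pair_full <- function(Q) {
  m <- min(Q)
  idx <- which(Q <= m, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  c(idx[1, 1], idx[1, 2])
}

# non-negative least squares fit of circular split weights to distances
circular_split_weights <- function(D, ord, tol) {
  n <- length(ord)
  split_sets <- list()
  for (i in seq_len(n - 1L)) {
    for (j in i:(n - 1L)) {
      split_sets[[length(split_sets) + 1L]] <- sort(ord[i:j])
    }
  }
  pairs <- utils::combn(n, 2L)
  n_pairs <- ncol(pairs)
  A <- matrix(0, n_pairs, length(split_sets))
  member <- vapply(split_sets, function(s) {
    v <- logical(n); v[s] <- TRUE; v
  }, logical(n))
  for (p in seq_len(n_pairs)) {
    A[p, ] <- xor(member[pairs[1, p], ], member[pairs[2, p], ])
  }
  dvec <- D[t(pairs)]
  fit <- pracma::lsqnonneg(A, dvec)
  w <- fit$x
  keep <- w > tol
  list(splits = split_sets[keep], weights = w[keep],
       resnorm = sqrt(max(fit$resnorm, 0)))
}

#' Pairwise distance implied by a split system
#'
#' Sum of the weights of the splits separating each taxon pair; for a
#' circular-decomposable metric this reproduces the input distances.
#'
#' @param ss a \code{SplitSystem}.
#' @return symmetric matrix over the taxa.
#' @export
split_system_distances <- function(ss) {
  n <- length(ss$taxa)
  M <- matrix(0, n, n, dimnames = list(ss$taxa, ss$taxa))
  for (k in seq_along(ss$splits)) {
    s <- ss$splits[[k]]
    v <- logical(n); v[s] <- TRUE
    sep <- outer(v, v, xor)
    M <- M + ss$weights[k] * sep
  }
  M
}

#' Haplotype cluster-cohesion score
#'
#' Quantifies whether a labeled group of taxa clusters together in distance
#' space: \code{score = 1 - mean(within) / mean(between)} over the two
#' groups' pairwise distances — near 1 for tight, well-separated clusters,
#' near 0 when labels are exchangeable. A label-permutation p-value
#' (one-sided, large scores extreme) is attached. A singleton group
#' contributes no within-group pairs; its side of the mean is skipped and
#' the result flagged.
#'
#' @param d a \code{DistanceMatrix}.
#' @param labels logical or two-level factor over the taxa (TRUE/first
#'   level = focal group).
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @return list with \code{score}, \code{p_value}, \code{n_perm},
#'   \code{flag_singleton}.
#' @export
cluster_cohesion <- function(d, labels, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(d, "DistanceMatrix"))
  lab <- if (is.logical(labels)) labels else {
    as.integer(factor(labels)) == 1L
  }
  n <- length(d$taxa)
  stopifnot(length(lab) == n)
  if (!any(lab) || all(lab)) stop("both groups must be non-empty",
                                  call. = FALSE)
  score_fn <- function(lab) {
    within <- c(d$d[lab, lab][upper.tri(d$d[lab, lab])],
                d$d[!lab, !lab][upper.tri(d$d[!lab, !lab])])
    between <- d$d[lab, !lab]
    mb <- mean(between)
    if (!length(within)) return(NA_real_)
    if (mb == 0) return(0)
    1 - mean(within) / mb
  }
  flag_singleton <- sum(lab) == 1L || sum(!lab) == 1L
  obs <- score_fn(lab)
  local_rng(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (score_fn(sample(lab)) >= obs - 1e-12) ge <- ge + 1L
  }
  list(score = obs, p_value = (1 + ge) / (n_perm + 1), n_perm = n_perm,
       flag_singleton = flag_singleton)
}

#' Haplotype p-distances on concatenated marker columns
#'
#' Uncorrected proportion of differing alleles between every pair of
#' haplotypes over the given markers — the distance used for haplotype
#' networks.
#'
#' @param h a \code{HaplotypeMatrix}.
#' @param markers optional marker subset.
#' @return a \code{DistanceMatrix} over haplotypes.
#' @export
haplotype_distances <- function(h, markers = NULL) {
  H <- if (is.null(markers)) h$haps else {
    mi <- vapply(markers, marker_index, 1L, map = h$map)
    h$haps[, mi, drop = FALSE]
  }
  n <- nrow(H)
  D <- matrix(0, n, n, dimnames = list(h$hap_ids, h$hap_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- mean(H[i, ] != H[j, ])
    }
  }
  as_distance_matrix(D)
}

#' Write a split system as a SplitsTree-compatible NEXUS file
#' @param ss a \code{SplitSystem}.
#' @param path output path.
#' @export
write_splits_nexus <- function(ss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(ss$taxa)
  writeLines(c("#nexus", "", "BEGIN Taxa;",
               sprintf("DIMENSIONS ntax=%d;", n), "TAXLABELS"), con)
  writeLines(sprintf("[%d] '%s'", seq_len(n), ss$taxa), con)
  writeLines(c(";", "END;", "", "BEGIN Splits;",
               sprintf("DIMENSIONS ntax=%d nsplits=%d;", n,
                       length(ss$splits)),
               "FORMAT labels=no weights=yes confidences=no intervals=no;",
               sprintf("CYCLE %s;", paste(ss$order, collapse = " ")),
               "MATRIX"), con)
  for (k in seq_along(ss$splits)) {
    writeLines(sprintf("[%d, size: %d] \t%.10g \t %s,", k,
                       length(ss$splits[[k]]), ss$weights[k],
                       paste(ss$splits[[k]], collapse = " ")), con)
  }
  writeLines(c(";", "END;"), con)
  invisible(path)
}
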