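#' Parsimony-informative sites of an alignment
#'
#' A site is informative when, ignoring gaps and ambiguity codes, it shows
#' at least two distinct states each carried by at least two sequences.
#' These are the sites on which the pairwise homoplasy test operates.
#'
#' @param aln a \code{SequenceAlignment}.
#' @return integer vector of 1-based site indices.
#' @export
informative_sites <- function(aln) {
  stopifnot(inherits(aln, "SequenceAlignment"))
  if (n_sequences(aln) < 4L) {
    warning("fewer than 4 sequences: the homoplasy test has no power")
  }
  m <- alignment_matrix(aln)
  m[!matrix(is_acgt(m), nrow(m))] <- NA
  which(vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    sum(tab >= 2L) >= 2L
  }, TRUE))
}

#' Refined incompatibility score of a site pair
#'
#' The minimum number of extra mutations (homoplasies) that any tree must
#' carry to explain the two characters jointly, beyond the parsimony minimum
#' of each alone. Computed on the partition-intersection (bipartite state)
#' graph: vertices are the states at the two sites, edges the observed joint
#' state pairs, and the score is \code{|E| - |V| + components}. Zero iff the
#' pair is compatible; for two binary sites this is exactly the four-gamete
#' test. Sequences with a gap/ambiguity (NA) at either site are dropped
#' pairwise.
#'
#' @param x,y state vectors over the same sequences (characters or
#'   integers; NA = excluded).
#' @return integer score (>= 0).
#' @export
pair_incompatibility <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) return(0L)
  xs <- match(x, sort(unique(x)))
  ys <- match(y, sort(unique(y)))
  n_x <- max(xs)
  edges <- unique(xs * 1000L + ys)
  n_e <- length(edges)
  n_v <- n_x + max(ys)
  # union-find over the bipartite vertex set
  parent <- seq_len(n_v)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in edges) {
    a <- find(e %/% 1000L)
    b <- find(n_x + e %% 1000L)
    if (a != b) parent[a] <- b
  }
  comps <- length(unique(vapply(seq_len(n_v), find, 1L)))
  as.integer(n_e - n_v + comps)
}

# per-site state vectors (NA for gap/ambiguity) and state counts for the
# informative sites of an alignment
site_states <- function(aln, sites) {
  m <- alignment_matrix(aln)[, sites, drop = FALSE]
  m[!matrix(is_acgt(m), nrow(m))] <- NA
  m
}

# normalized incompatibility matrix over informative sites: entry (i, j) is
# score / (min(k_i, k_j) - 1), the score's maximum for those state counts.
# Binary/binary pairs (the bulk) take the four-gamete fast path; multi-state
# pairs fall back to the bipartite-graph score.
phi_score_matrix <- function(states) {
  k_sites <- ncol(states)
  S <- matrix(0, k_sites, k_sites)
  if (k_sites < 2L) return(S)
  codes <- lapply(seq_len(k_sites), function(j) {
    x <- states[, j]
    match(x, sort(unique(x[!is.na(x)])))
  })
  ks <- vapply(codes, function(x) max(x, 0L, na.rm = TRUE), 1L)
  for (i in seq_len(k_sites - 1L)) {
    xi <- codes[[i]]
    for (j in (i + 1L):k_sites) {
      yj <- codes[[j]]
      keep <- !is.na(xi) & !is.na(yj)
      x <- xi[keep]; y <- yj[keep]
      if (!length(x)) next
      n_joint <- length(unique((x - 1L) * 8L + y))
      if (ks[i] == 2L && ks[j] == 2L) {
        # four-gamete test; compatible unless all 4 joint states observed
        if (n_joint == 4L) S[i, j] <- S[j, i] <- 1
      } else {
        mx <- min(ks[i], ks[j]) - 1L
        if (mx > 0L) {
          sc <- pair_incompatibility(x, y) / mx
          if (sc > 0) S[i, j] <- S[j, i] <- sc
        }
      }
    }
  }
  S
}

#' Windowed pairwise homoplasy statistic
#'
#' Mean normalized refined-incompatibility score over all informative-site
#' pairs whose alignment positions are at most \code{window_w} bp apart.
#' Each pair is normalized by its maximum possible score
#' \code{min(k_i, k_j) - 1} (k = number of states). Recombination makes
#' nearby sites more compatible than the genome-wide mixture, so a *small*
#' observed value relative to a site-order permutation null is the
#' recombination signal.
#'
#' @param aln a \code{SequenceAlignment}.
#' @param window_w window width in alignment bp (default 100, the
#'   conventional setting).
#' @return list with \code{phi}, \code{n_informative}, \code{n_pairs};
#'   \code{phi} is NA when fewer than 2 informative sites or no pair falls
#'   within the window.
#' @export
phi_statistic <- function(aln, window_w = 100) {
  sites <- informative_sites_quiet(aln)
  states <- site_states(aln, sites)
  S <- phi_score_matrix(states)
  mask <- window_mask(sites, window_w)
  n_pairs <- sum(mask)
  phi <- if (length(sites) < 2L || n_pairs == 0L) NA_real_ else {
    mean(S[mask])
  }
  list(phi = phi, n_informative = length(sites), n_pairs = n_pairs)
}

informative_sites_quiet <- function(aln) {
  suppressWarnings(informative_sites(aln))
}

# upper-triangle logical mask of site pairs within window_w bp
window_mask <- function(positions, window_w) {
  k <- length(positions)
  if (k < 2L) return(matrix(FALSE, k, k))
  dd <- abs(outer(positions, positions, "-"))
  dd <= window_w & upper.tri(dd)
}

#' Phi permutation test for recombination
#'
#' Permutes the assignment of informative sites to their alignment
#' positions, recomputing the windowed statistic each time; the p-value is
#' \code{(1 + #\{permuted phi <= observed phi\}) / (n_perm + 1)}. Under
#' clonal evolution nearby and distant site pairs are exchangeable and p is
#' uniform; under recombination the observed windowed mean is in the lower
#' tail. When the statistic is undefined (fewer than 2 informative sites or
#' no in-window pair) p = 1 by convention.
#'
#' @param aln a \code{SequenceAlignment}.
#' @param window_w window width in bp.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed (required for reproducibility).
#' @return a \code{PhiResult}: list with \code{phi_observed}, \code{p_value},
#'   \code{n_informative}, \code{n_perm}, \code{window_w},
#'   \code{incompatible_pairs} (data.frame of site pairs with nonzero score).
#' @export
phi_permutation_test <- function(aln, window_w = 100, n_perm = 1000L,
                                 seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  sites <- informative_sites_quiet(aln)
  states <- site_states(aln, sites)
  S <- phi_score_matrix(states)
  mask <- window_mask(sites, window_w)
  k <- length(sites)

  nz <- which(S > 0 & upper.tri(S), arr.ind = TRUE)
  inc_pairs <- data.frame(site_i = sites[nz[, 1]], site_j = sites[nz[, 2]],
                          score = S[nz])

  if (k < 2L || sum(mask) == 0L) {
    return(phi_result(NA_real_, 1, k, n_perm, window_w, inc_pairs))
  }
  obs <- mean(S[mask])
  idx <- which(mask, arr.ind = TRUE)   # in-window pairs in position space
  ii <- idx[, 1]; jj <- idx[, 2]
  local_rng(seed)
  perm_le <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(k)
    val <- mean(S[cbind(p[ii], p[jj])])
    if (val <= obs + 1e-12) perm_le <- perm_le + 1L
  }
  p_value <- (1 + perm_le) / (n_perm + 1)
  phi_result(obs, p_value, k, n_perm, window_w, inc_pairs)
}

phi_result <- function(phi, p, k, n_perm, window_w, inc_pairs) {
  structure(list(phi_observed = phi, p_value = p, n_informative = k,
                 n_perm = n_perm, window_w = window_w,
                 incompatible_pairs = inc_pairs),
            class = "PhiResult")
}

#' @export
print.PhiResult <- function(x, ...) {
  cat(sprintf(
    "Phi test: %d informative sites, phi = %s, p = %.4g (%d permutations, window %g bp)\n",
    x$n_informative,
    if (is.na(x$phi_observed)) "NA" else format(x$phi_observed, digits = 4),
    x$p_value, x$n_perm, x$window_w))
  invisible(x)
}

#' Write a PhiResult as JSON
#' @param x a \code{PhiResult}.
#' @param path output path.
#' @export
write_phi_result <- function(x, path) {
  jsonlite::write_json(
    list(n_informative = x$n_informative, phi = x$phi_observed,
         p_value = x$p_value, n_perm = x$n_perm, window_w = x$window_w),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
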