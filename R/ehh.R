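#' Extended haplotype homozygosity around a core allele
#'
#' Among the haplotypes carrying \code{core_allele} at the core marker, EHH
#' at a flanking marker is the probability that two randomly drawn carriers
#' are identical at every marker between the core and that position:
#' \code{EHH(x) = sum_h C(n_h, 2) / C(n_a, 2)} over the prefix-haplotype
#' classes h. The curve is evaluated at marker positions, independently left
#' and right, and each side stops at the first marker where EHH falls below
#' \code{stop_threshold} (that marker included) or at the chromosome end.
#' EHH is 1 at the core and non-increasing outward.
#'
#' @param h a \code{HaplotypeMatrix} (complete data by contract).
#' @param core_marker marker id or index.
#' @param core_allele allele code at the core marker.
#' @param stop_threshold EHH level below which a side stops (default 0.05).
#' @return an \code{EHHResult}: list with \code{core_marker},
#'   \code{core_allele}, \code{n_carriers}, \code{curve} (data.frame: side,
#'   pos, ehh, including the core point on both sides), \code{ihh_left},
#'   \code{ihh_right}, \code{ihh_total}; or a not-computable result
#'   (\code{computable = FALSE}) when fewer than 2 haplotypes carry the
#'   allele.
#' @export
ehh_curve <- function(h, core_marker, core_allele, stop_threshold = 0.05) {
  mi <- marker_index(h$map, core_marker)
  carriers <- which(h$haps[, mi] == core_allele)
  n_a <- length(carriers)
  if (n_a < 2L) {
    return(structure(list(core_marker = h$map$id[mi],
                          core_allele = core_allele, n_carriers = n_a,
                          computable = FALSE, curve = NULL,
                          ihh_left = NA_real_, ihh_right = NA_real_,
                          ihh_total = NA_real_),
                     class = "EHHResult"))
  }
  H <- h$haps[carriers, , drop = FALSE]
  pos <- h$map$pos
  denom <- choose(n_a, 2)

  side_curve <- function(idx_seq, side) {
    grp <- rep(1L, n_a)
    out_pos <- numeric(0); out_ehh <- numeric(0)
    for (j in idx_seq) {
      key <- paste(grp, H[, j])
      grp <- match(key, unique(key))
      tab <- tabulate(grp)
      e <- sum(choose(tab, 2)) / denom
      out_pos <- c(out_pos, pos[j]); out_ehh <- c(out_ehh, e)
      if (e < stop_threshold) break
    }
    data.frame(side = side, pos = c(pos[mi], out_pos),
               ehh = c(1, out_ehh), stringsAsFactors = FALSE)
  }
  left <- side_curve(rev(seq_len(mi - 1L)), "left")
  right <- side_curve(seq_len(ncol(H))[-seq_len(mi)], "right")
  ihh_l <- trapezoid_ihh(left$pos, left$ehh)
  ihh_r <- trapezoid_ihh(right$pos, right$ehh)
  structure(list(core_marker = h$map$id[mi], core_allele = core_allele,
                 n_carriers = n_a, computable = TRUE,
                 curve = rbind(left, right),
                 ihh_left = ihh_l, ihh_right = ihh_r,
                 ihh_total = ihh_l + ihh_r),
            class = "EHHResult")
}

trapezoid_ihh <- function(pos, ehh) {
  if (length(pos) < 2L) return(0)
  sum(abs(diff(pos)) * (utils::head(ehh, -1) + utils::tail(ehh, -1)) / 2)
}

#' @export
print.EHHResult <- function(x, ...) {
  if (!isTRUE(x$computable)) {
    cat(sprintf("EHH at %s allele %s: not computable (%d carrier%s)\n",
                x$core_marker, x$core_allele, x$n_carriers,
                if (x$n_carriers == 1L) "" else "s"))
  } else {
    cat(sprintf(
      "EHH at %s allele %s: %d carriers, iHH left/right/total = %.0f/%.0f/%.0f bp\n",
      x$core_marker, x$core_allele, x$n_carriers,
      x$ihh_left, x$ihh_right, x$ihh_total))
  }
  invisible(x)
}

#' Integrated EHH
#'
#' Trapezoidal integral of the EHH curve over physical distance, per side
#' from the core to the last evaluated marker; total is left + right. Units
#' are bp (EHH is dimensionless).
#'
#' @param e an \code{EHHResult}.
#' @return list with \code{left}, \code{right}, \code{total}.
#' @export
ihh <- function(e) {
  stopifnot(inherits(e, "EHHResult"))
  if (!isTRUE(e$computable)) {
    stop("EHH not computable for this core allele", call. = FALSE)
  }
  list(left = e$ihh_left, right = e$ihh_right, total = e$ihh_total)
}

#' Haplotype bifurcation tree around a core allele
#'
#' Moving marker by marker away from the core, carrier haplotypes split
#' whenever they differ at the next marker; the tree records, per node, the
#' marker reached and the number of haplotypes still together. Children are
#' ordered deterministically by allele code (0 before 1). Few, late splits
#' indicate a long conserved haplotype.
#'
#' @param h a \code{HaplotypeMatrix}.
#' @param core_marker marker id or index.
#' @param core_allele allele code at the core.
#' @param max_markers markers to extend per side.
#' @return a \code{BifurcationTree}: list with \code{left}/\code{right}
#'   node tables (id, parent, marker, pos, count, allele) and counts
#'   conserved at every depth.
#' @export
bifurcation_tree <- function(h, core_marker, core_allele,
                             max_markers = Inf) {
  mi <- marker_index(h$map, core_marker)
  carriers <- which(h$haps[, mi] == core_allele)
  n_a <- length(carriers)
  if (n_a < 1L) stop("no haplotype carries the core allele", call. = FALSE)
  H <- h$haps[carriers, , drop = FALSE]
  pos <- h$map$pos

  side_tree <- function(idx_seq) {
    nodes <- data.frame(id = 1L, parent = NA_integer_, marker = h$map$id[mi],
                        pos = pos[mi], count = n_a, allele = NA_integer_,
                        stringsAsFactors = FALSE)
    node_of <- rep(1L, n_a)
    next_id <- 1L
    steps <- 0L
    for (j in idx_seq) {
      steps <- steps + 1L
      if (steps > max_markers) break
      for (par in sort(unique(node_of))) {
        members <- which(node_of == par)
        alleles <- sort(unique(H[members, j]))
        for (al in alleles) {
          next_id <- next_id + 1L
          sub <- members[H[members, j] == al]
          nodes <- rbind(nodes, data.frame(
            id = next_id, parent = par, marker = h$map$id[j], pos = pos[j],
            count = length(sub), allele = al, stringsAsFactors = FALSE))
          node_of[sub] <- next_id
        }
      }
    }
    nodes
  }
  structure(list(core_marker = h$map$id[mi], core_allele = core_allele,
                 n_carriers = n_a,
                 left = side_tree(rev(seq_len(mi - 1L))),
                 right = side_tree(seq_len(ncol(H))[-seq_len(mi)])),
            class = "BifurcationTree")
}

#' @export
print.BifurcationTree <- function(x, ...) {
  n_split <- function(nodes) {
    if (is.null(nodes)) return(0L)
    sum(table(nodes$parent[!is.na(nodes$parent)]) > 1L)
  }
  cat(sprintf("BifurcationTree at %s allele %s: %d carriers, %d/%d splits (left/right)\n",
              x$core_marker, x$core_allele, x$n_carriers,
              n_split(x$left), n_split(x$right)))
  invisible(x)
}

#' Export an EHH curve as TSV
#' @param e an \code{EHHResult}.
#' @param path output path.
#' @export
write_ehh_curve <- function(e, path) {
  stopifnot(isTRUE(e$computable))
  utils::write.table(e$curve, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Export a bifurcation tree
#'
#' JSON (both sides, full node tables) or annotated newick (one side,
#' haplotype counts as node labels).
#'
#' @param bt a \code{BifurcationTree}.
#' @param path output path.
#' @param format \code{"json"} or \code{"newick"}.
#' @param side for newick, \code{"left"} or \code{"right"}.
#' @export
write_bifurcation_tree <- function(bt, path, format = c("json", "newick"),
                                   side = "right") {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(core_marker = bt$core_marker, core_allele = bt$core_allele,
           n_carriers = bt$n_carriers, left = bt$left, right = bt$right),
      path, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  } else {
    nodes <- bt[[side]]
    build <- function(id) {
      kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
      lab <- nodes$count[nodes$id == id]
      if (!length(kids)) return(as.character(lab))
      paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")", lab)
    }
    writeLines(paste0(build(1L), ";"), path)
  }
  invisible(path)
}
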