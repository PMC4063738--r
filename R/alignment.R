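#' Sequence alignment container
#'
#' A \code{SequenceAlignment} is a set of named, equal-length DNA sequences
#' (gaps \code{-} and IUPAC ambiguity codes allowed). It is the unit on which
#' divergence, allele sharing, the Phi recombination test and tree/network
#' construction operate.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return An object of class \code{SequenceAlignment} with elements
#'   \code{names}, \code{seqs} (upper-case character vector) and
#'   \code{length} (alignment width in bp).
#' @export
sequence_alignment <- function(seqs) {
  if (length(seqs) < 1L) {
    stop("alignment must contain at least one sequence", call. = FALSE)
  }
  nm <- names(seqs)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("sequences must carry unique non-empty names", call. = FALSE)
  }
  seqs <- toupper(as.character(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must all have the same length (got lengths ",
         paste(sort(unique(widths)), collapse = ", "), ")", call. = FALSE)
  }
  if (widths[1] < 1L) stop("alignment length must be >= 1", call. = FALSE)
  bad <- grepl("[^ACGTUMRWSYKVHDBN.-]", seqs)
  if (any(bad)) {
    stop("unexpected characters in sequence(s): ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- nm
  structure(list(names = nm, seqs = seqs, length = unname(widths[1])),
            class = "SequenceAlignment")
}

#' @export
print.SequenceAlignment <- function(x, ...) {
  cat("SequenceAlignment:", length(x$names), "sequences x", x$length, "bp\n")
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln a \code{SequenceAlignment}.
#' @export
n_sequences <- function(aln) length(aln$names)

#' Alignment as a character matrix (sequences x sites)
#'
#' @param aln a \code{SequenceAlignment}.
#' @return character matrix with one row per sequence, one column per site.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$names
  m
}

#' Subset an alignment by sequence name or index
#' @param aln a \code{SequenceAlignment}.
#' @param which names or indices of sequences to keep.
#' @export
subset_alignment <- function(aln, which) {
  sequence_alignment(aln$seqs[which])
}

#' Read a multi-FASTA alignment
#'
#' Reads a FASTA file, normalizes to upper case, and enforces the alignment
#' contract (equal lengths, unique names). Names are the first whitespace
#' token of each header.
#'
#' @param path path to a FASTA file.
#' @return a \code{SequenceAlignment}.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, call. = FALSE))
  if (length(set) < 1L) stop("FASTA file contains no records: ", path,
                             call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  sequence_alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln a \code{SequenceAlignment}.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta_alignment <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$names)) {
    writeLines(paste0(">", aln$names[i]), con)
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## site masks -----------------------------------------------------------------

# TRUE where the character is an unambiguous base
is_acgt <- function(x) x %in% c("A", "C", "G", "T", "U")

# TRUE where the character is a gap
is_gap <- function(x) x %in% c("-", ".")
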