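## Alphabets ------------------------------------------------------------------

#' The 20 standard amino acids
#'
#' One-letter codes of the standard residues, in alphabetical order. The
#' extended protein alphabet used throughout the package adds the gap
#' character `"-"`, the null character `"O"` (a residue suppressed because its
#' codon is CpG-decay-affected) and `"X"` (position below the consensus
#' threshold, or an untranslatable codon).
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PROTEIN_EXT <- c(AA20, "-", "O", "X")
DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Coerce sequences to an alignment matrix
#'
#' Accepts a named character vector of equal-length sequence strings, a
#' character matrix (rows = sequences), or an alignment returned by
#' [read_alignment()], and returns a character matrix with one row per
#' sequence and one column per alignment position.
#'
#' @param x Sequences in any of the accepted forms.
#' @return Character matrix with rownames set to sequence ids.
#' @export
as_alignment_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "character"
    if (is.null(rownames(x)) && nrow(x) > 0L)
      rownames(x) <- paste0("seq", seq_len(nrow(x)))
    return(x)
  }
  if (!is.character(x)) stop("cannot interpret input as an alignment")
  lens <- nchar(x)
  if (length(unique(lens)) > 1L) {
    bad <- names(x)[which(lens != lens[1L])[1L]]
    stop("ragged alignment: record '", bad, "' has length ",
         lens[which(lens != lens[1L])[1L]], ", expected ", lens[1L])
  }
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- ids
  m
}

#' Collapse an alignment matrix back to sequence strings
#'
#' @param m Character matrix as returned by [as_alignment_matrix()].
#' @return Named character vector of sequence strings.
#' @export
alignment_strings <- function(m) {
  m <- as_alignment_matrix(m)
  stats::setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

validate_alphabet <- function(m, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  allowed <- if (alphabet == "dna") DNA_ALPHABET else PROTEIN_EXT
  badm <- matrix(!(m %in% allowed), nrow = nrow(m))
  bad <- which(badm, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("illegal character '", m[i, j], "' for alphabet '", alphabet,
         "' in record '", rownames(m)[i], "' at position ", j)
  }
  invisible(m)
}

## FASTA ----------------------------------------------------------------------

#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file, validates that every record has the same
#' length and that all characters belong to the declared alphabet. Record ids
#' are taken from the headers up to the first whitespace and must be unique.
#' The legacy gap character `"."` is normalized to `"-"` on read.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` (20 residues plus `-`, `O`, `X`) or `"dna"`.
#' @return Character matrix, rows = records, rownames = ids.
#' @export
read_alignment <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in '", path, "': ", ids[duplicated(ids)][1L])
  seqs <- stats::setNames(toupper(as.character(ss)), ids)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1L])[1L]
    stop("ragged alignment in '", path, "': record '", ids[off],
         "' has length ", lens[off], ", expected ", lens[1L])
  }
  m <- as_alignment_matrix(seqs)
  validate_alphabet(m, alphabet)
  m
}

#' Write an alignment to FASTA
#'
#' @param aln Alignment (matrix or named character vector).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  seqs <- alignment_strings(as_alignment_matrix(aln))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

## Cluster tables -------------------------------------------------------------

#' Write a cluster assignment as a TSV table
#'
#' Columns are `id`, `family`, `cluster_tag`; one row per sequence.
#'
#' @param assignment A `cluster_assignment` (see [kmeans_cluster()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_table <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  df <- data.frame(
    id = names(assignment$labels),
    family = rep(as.character(assignment$family %||% NA_character_),
                 length(assignment$labels)),
    cluster_tag = unname(assignment$tags[assignment$labels]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster table written by [write_cluster_table()]
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `family`, `cluster_tag`.
#' @export
read_cluster_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Consensus naming -----------------------------------------------------------

#' Construct a consensus name descriptor
#'
#' Cluster consensuses follow the `cLn.n` convention: cluster number followed
#' by family number (`cL3.5` is cluster 3 of the L1Pa5 family). CG-null
#' consensuses carry an `_o` suffix and keep the `cL` prefix (`cL3.5_o`);
#' CG-restored consensuses are written without the prefix and with an `rt`
#' suffix (`1.7rt`).
#'
#' @param variant `"cgnull"` or `"restored"`.
#' @param cluster Cluster number, or `NULL` when the name has no cluster tag.
#' @param family Family number (required with `cluster`).
#' @param base_name Base name used when there is no cluster tag.
#' @return Object of class `named_consensus`.
#' @export
named_consensus <- function(variant = c("cgnull", "restored"),
                            cluster = NULL, family = NULL, base_name = NULL) {
  variant <- match.arg(variant)
  if (!is.null(cluster) && is.null(family))
    stop("a cluster tag requires a family number")
  if (is.null(cluster) && is.null(base_name))
    stop("either a cluster tag or a base_name is required")
  structure(list(variant = variant, cluster = cluster, family = family,
                 base_name = base_name),
            class = "named_consensus")
}

#' Render a consensus name
#'
#' @param nc A [named_consensus()] descriptor.
#' @return Character scalar, e.g. `"cL3.5_o"` or `"1.7rt"`.
#' @export
render_name <- function(nc) {
  stopifnot(inherits(nc, "named_consensus"))
  if (!is.null(nc$cluster)) {
    if (nc$variant == "cgnull")
      sprintf("cL%d.%d_o", as.integer(nc$cluster), as.integer(nc$family))
    else
      sprintf("%d.%drt", as.integer(nc$cluster), as.integer(nc$family))
  } else {
    paste0(nc$base_name, if (nc$variant == "cgnull") "_o" else "rt")
  }
}

#' @export
print.named_consensus <- function(x, ...) {
  cat("<named_consensus>", render_name(x), "\n")
  invisible(x)
}
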