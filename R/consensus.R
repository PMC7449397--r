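## Threshold consensus construction over the extended protein alphabet.
##
## Denominator convention: "O" (CG-null), "X" and "-" are missing data, so a
## column's threshold test is taken over informative residues only. A column
## is emitted as "-" (or "O") only when that character is the absolute
## majority of all rows. Ties at exactly the threshold pass (>=); ties
## between two equally frequent top residues yield "X".

column_consensus_char <- function(col, threshold) {
  n <- length(col)
  if (sum(col == "-") > n / 2) return(list(ch = "-", support = NA_real_))
  if (sum(col == "O") > n / 2) return(list(ch = "O", support = NA_real_))
  obs <- col[col %in% AA20]
  if (length(obs) == 0L) return(list(ch = "X", support = NA_real_))
  tab <- sort(table(obs), decreasing = TRUE)
  top <- tab[1L] / length(obs)
  if (top < threshold) return(list(ch = "X", support = unname(top)))
  if (length(tab) > 1L && tab[2L] == tab[1L])
    return(list(ch = "X", support = unname(top)))   # tied winners
  list(ch = names(tab)[1L], support = unname(top))
}

#' Threshold consensus of a peptide alignment
#'
#' Per column: the most frequent standard residue if its frequency among
#' informative residues reaches `threshold`, else `"X"`. Gap (or null)
#' columns are emitted as `"-"` (or `"O"`) only when that character is the
#' absolute majority of all rows.
#'
#' @param peptides Protein alignment (matrix or named vector).
#' @param threshold Fraction in (0, 1]; 0.5 gives the usual 50% consensus,
#'   0.6 the stricter 60% consensus used for ancestral resuscitation.
#' @param name Optional [named_consensus()] descriptor or character name.
#' @return Object of class `consensus_record` with fields `name`, `seq`,
#'   `threshold` and `support` (per-position winning-residue frequency, `NA`
#'   at gap/null columns).
#' @export
threshold_consensus <- function(peptides, threshold = 0.5, name = NULL) {
  m <- as_alignment_matrix(peptides)
  if (nrow(m) == 0L) stop("empty alignment")
  stopifnot(threshold > 0, threshold <= 1)
  cols <- lapply(seq_len(ncol(m)), function(j)
    column_consensus_char(m[, j], threshold))
  structure(list(
    name = name,
    seq = paste0(vapply(cols, `[[`, character(1), "ch"), collapse = ""),
    threshold = threshold,
    support = vapply(cols, `[[`, numeric(1), "support")
  ), class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  nm <- if (inherits(x$name, "named_consensus")) render_name(x$name)
        else x$name %||% "<unnamed>"
  cat("<consensus_record> ", nm, " (threshold ", x$threshold, ")\n",
      x$seq, "\n", sep = "")
  invisible(x)
}

#' CG-null / CG-restored consensus pair
#'
#' Computes the `_o` consensus on CG-null peptides, then builds the matching
#' `rt` consensus by replacing every `"O"` position with the translation of
#' the CG-restored nucleotide consensus codon at that position.
#'
#' @param peptides_cgnull CG-null protein alignment (see
#'   [cg_null_translate_alignment()]).
#' @param codon_aln The corresponding codon alignment (same records, one
#'   codon column per peptide column).
#' @param threshold Consensus threshold.
#' @param cluster,family Optional cluster tag numbers for naming.
#' @param base_name Base name used when no cluster tag is given.
#' @param min_cg Minimum CG observations for restoration.
#' @return List with elements `o` and `rt`, both `consensus_record`s.
#' @export
consensus_pair <- function(peptides_cgnull, codon_aln, threshold = 0.5,
                           cluster = NULL, family = NULL, base_name = NULL,
                           min_cg = 2L) {
  pep <- as_alignment_matrix(peptides_cgnull)
  nt <- as_alignment_matrix(codon_aln)
  if (ncol(nt) != 3L * ncol(pep))
    stop("coordinate mismatch: codon alignment has ", ncol(nt),
         " nt columns, expected ", 3L * ncol(pep))
  if (!setequal(rownames(nt), rownames(pep)))
    stop("coordinate mismatch: peptide and codon alignments name different records")
  nt <- nt[rownames(pep), , drop = FALSE]

  mk_name <- function(variant) {
    if (is.null(cluster) && is.null(base_name)) return(NULL)
    named_consensus(variant, cluster = cluster, family = family,
                    base_name = base_name)
  }
  cons_o <- threshold_consensus(pep, threshold, name = mk_name("cgnull"))

  rt_chars <- strsplit(cons_o$seq, "")[[1]]
  null_pos <- which(rt_chars == "O")
  if (length(null_pos)) {
    nt_cons <- strsplit(nt_consensus(nt, restore_cg = TRUE, min_cg = min_cg),
                        "")[[1]]
    for (p in null_pos) {
      codon <- nt_cons[(3L * (p - 1L) + 1L):(3L * p)]
      rt_chars[p] <- translate_one_codon(codon)
    }
  }
  cons_rt <- structure(list(
    name = mk_name("restored"),
    seq = paste0(rt_chars, collapse = ""),
    threshold = threshold,
    support = cons_o$support
  ), class = "consensus_record")

  list(o = cons_o, rt = cons_rt)
}

#' Position-by-residue frequency matrix
#'
#' Per-column relative frequencies of the 20 standard residues over
#' informative rows (gap, `"O"` and `"X"` excluded from the denominator).
#' Rows sum to 1; columns with no informative residue are all zero and
#' flagged in the `"uninformative"` attribute. The table is suitable for
#' TSV export and external sequence-LOGO rendering.
#'
#' @param peptides Protein alignment.
#' @return Numeric matrix, `L` positions x 20 residues, with attribute
#'   `uninformative` (integer positions).
#' @export
frequency_matrix <- function(peptides) {
  m <- as_alignment_matrix(peptides)
  if (nrow(m) == 0L) stop("empty alignment")
  fm <- matrix(0, nrow = ncol(m), ncol = length(AA20),
               dimnames = list(seq_len(ncol(m)), AA20))
  empty <- integer(0)
  for (j in seq_len(ncol(m))) {
    obs <- m[, j][m[, j] %in% AA20]
    if (length(obs) == 0L) { empty <- c(empty, j); next }
    tab <- table(factor(obs, levels = AA20))
    fm[j, ] <- as.numeric(tab) / length(obs)
  }
  attr(fm, "uninformative") <- empty
  fm
}

#' Write a frequency matrix as TSV
#'
#' @param fm Matrix from [frequency_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_frequency_matrix <- function(fm, path) {
  df <- data.frame(position = as.integer(rownames(fm)), fm,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
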