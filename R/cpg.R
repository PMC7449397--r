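## CpG-decay-aware translation and CG restoration.
##
## Ancient L1 copies are neutrally decaying pseudogenes in which methylated
## CG dinucleotides mutate to TG (or CA on the opposite strand) at a strongly
## elevated rate. Codons touching a CG -- CGN, NCG, or either side of a
## cross-codon NNC|GNN junction -- therefore carry amino acid variation that
## reflects post-insertion decay, not the variation present while the family
## was replicating. These functions suppress that signal (CG-null
## translation, null character "O") and put it back when reconstructing
## ancestral consensuses (CG restoration).

split_codons <- function(seq, frame = 0L) {
  nt <- if (is.matrix(seq)) as.vector(seq) else strsplit(toupper(seq), "")[[1]]
  frame <- as.integer(frame)
  if (frame < 0L || frame > 2L) stop("frame must be 0, 1 or 2")
  if (frame > 0L) nt <- nt[-seq_len(frame)]
  if (length(nt) %% 3L != 0L)
    stop("out-of-frame input: ", length(nt),
         " nucleotides after frame offset is not a multiple of 3")
  matrix(nt, nrow = 3L)            # one column per codon
}

codon_is_gap <- function(cod) colSums(cod == "-") == 3L

check_partial_gaps <- function(cod) {
  g <- colSums(cod == "-")
  if (any(g > 0L & g < 3L))
    stop("frame error: codon ", which(g > 0L & g < 3L)[1L],
         " contains a partial gap (gaps must occur in multiples of 3)")
  invisible(cod)
}

#' Find CpG-decay-affected codon positions
#'
#' A residue is CG-affected when its codon matches `CGN` or `NCG`, or when it
#' flanks a cross-codon `C|G` junction (`NNC GNN`). For the junction the
#' default masks both flanking residues: the C is mutable by C->T and the G
#' by G->A, so either residue can carry decay noise
#' (`junction_mask = "both"`); `"left"`/`"right"` mask only one side.
#'
#' @param seq In-frame nucleotide sequence (string); gaps allowed in codon
#'   multiples.
#' @param frame Frame offset 0-2 removed before codon splitting.
#' @param junction_mask Which side(s) of an `NNC|GNN` junction to mask.
#' @return Sorted integer vector of affected residue positions (1-based in
#'   the aligned codon frame).
#' @export
cg_affected_positions <- function(seq, frame = 0L,
                                  junction_mask = c("both", "left", "right")) {
  junction_mask <- match.arg(junction_mask)
  cod <- check_partial_gaps(split_codons(seq, frame))
  n <- ncol(cod)
  gap <- codon_is_gap(cod)
  affected <- logical(n)
  # within-codon CG: CGN (pos 1-2) or NCG (pos 2-3)
  affected <- (cod[1L, ] == "C" & cod[2L, ] == "G") |
              (cod[2L, ] == "C" & cod[3L, ] == "G")
  # cross-codon junction between adjacent non-gap codons
  if (n > 1L) {
    j <- which(cod[3L, -n] == "C" & cod[1L, -1L] == "G" &
                 !gap[-n] & !gap[-1L])
    if (length(j)) {
      if (junction_mask %in% c("both", "left"))  affected[j] <- TRUE
      if (junction_mask %in% c("both", "right")) affected[j + 1L] <- TRUE
    }
  }
  affected[gap] <- FALSE
  which(affected)
}

translate_one_codon <- function(codon) {
  if (all(codon == "-")) return("-")
  key <- paste0(codon, collapse = "")
  aa <- Biostrings::GENETIC_CODE[key]
  if (is.na(aa)) return("X")        # ambiguous/unknown codon
  if (aa == "*") return("X")        # internal stop in a decayed copy
  unname(aa)
}

#' Translate codons with the standard genetic code
#'
#' Gap codons (`---`) translate to `"-"`; internal stop codons translate to
#' `"X"` with a warning (ancient decayed copies contain stops); codons with
#' ambiguous characters translate to `"X"`.
#'
#' @inheritParams cg_affected_positions
#' @return Amino acid string over the extended protein alphabet.
#' @export
translate_codons <- function(seq, frame = 0L) {
  cod <- check_partial_gaps(split_codons(seq, frame))
  aa <- vapply(seq_len(ncol(cod)), function(i) translate_one_codon(cod[, i]),
               character(1))
  keys <- apply(cod, 2L, paste0, collapse = "")
  stops <- sum(Biostrings::GENETIC_CODE[keys] == "*", na.rm = TRUE)
  if (stops > 0L)
    warning(stops, " internal stop codon(s) translated as 'X'")
  paste0(aa, collapse = "")
}

#' CG-null translation
#'
#' Standard-table translation in which every CG-affected residue (see
#' [cg_affected_positions()]) is replaced by the null amino acid character
#' `"O"`, so that downstream analyses treat decay-exposed positions as
#' missing data.
#'
#' @inheritParams cg_affected_positions
#' @return Amino acid string over the extended protein alphabet.
#' @export
cg_null_translate <- function(seq, frame = 0L,
                              junction_mask = c("both", "left", "right")) {
  junction_mask <- match.arg(junction_mask)
  aa <- strsplit(translate_codons(seq, frame), "")[[1]]
  idx <- cg_affected_positions(seq, frame, junction_mask)
  if (length(idx)) aa[idx] <- "O"
  paste0(aa, collapse = "")
}

#' Codon columns that are CG-affected in the family consensus
#'
#' Identifies the codon columns whose CG-restored nucleotide consensus (see
#' [nt_consensus()]) matches a CG-affected pattern. At a decayed column most
#' individual copies carry the decay product and no longer match the CG
#' patterns themselves, so family-level masking works on the restored
#' consensus: a column is CG-affected when the family as a whole shows the
#' CG-plus-decay-product signature, and that column is then nulled in every
#' record.
#'
#' @param codon_aln DNA alignment (matrix or named character vector) of
#'   in-frame coding sequences.
#' @param min_cg Minimum CG observations for restoration (see
#'   [nt_consensus()]).
#' @inheritParams cg_affected_positions
#' @return Sorted integer vector of affected codon columns.
#' @export
cg_affected_columns <- function(codon_aln, frame = 0L,
                                junction_mask = c("both", "left", "right"),
                                min_cg = 2L) {
  junction_mask <- match.arg(junction_mask)
  m <- as_alignment_matrix(codon_aln)
  cons <- nt_consensus(m, restore_cg = TRUE, min_cg = min_cg)
  cg_affected_positions(cons, frame, junction_mask)
}

#' CG-null translate every record of a codon alignment
#'
#' With `per = "column"` (the default for family-level analysis) the
#' columns found CG-affected in the CG-restored family consensus
#' ([cg_affected_columns()]) are nulled in every record, so post-insertion
#' decay products at those columns cannot masquerade as amino acid
#' variation. `per = "record"` masks each sequence only at its own
#' CG-affected codons.
#'
#' @param codon_aln DNA alignment (matrix or named character vector) of
#'   in-frame coding sequences.
#' @param per `"column"` or `"record"` masking (see Details).
#' @inheritParams cg_affected_positions
#' @return Protein alignment matrix over the extended alphabet.
#' @export
cg_null_translate_alignment <- function(codon_aln, frame = 0L,
                                        junction_mask = c("both", "left", "right"),
                                        per = c("column", "record")) {
  junction_mask <- match.arg(junction_mask)
  per <- match.arg(per)
  m <- as_alignment_matrix(codon_aln)
  pep <- withCallingHandlers(
    vapply(rownames(m), function(id)
      cg_null_translate(paste0(m[id, ], collapse = ""), frame, junction_mask),
      character(1)),
    warning = function(w) invokeRestart("muffleWarning"))
  out <- as_alignment_matrix(pep)
  if (per == "column") {
    cols <- cg_affected_columns(m, frame, junction_mask)
    if (length(cols)) {
      masks <- stats::setNames(rep(list(cols), nrow(out)), rownames(out))
      out <- apply_mask_to_peptides(out, masks)
    }
  }
  out
}

#' Apply CG masks to an aligned peptide set
#'
#' Positions listed in each record's mask are set to `"O"` (or directly to
#' `"-"`, i.e. missing data, with `to_missing = TRUE`). Gap positions are
#' never overwritten: the null character marks a suppressed residue, not a
#' deletion.
#'
#' @param peptides Protein alignment (matrix or named vector).
#' @param masks Named list of integer position vectors, one per record;
#'   names must match record ids.
#' @param to_missing Convert masked positions to `"-"` instead of `"O"`.
#' @return Masked protein alignment matrix.
#' @export
apply_mask_to_peptides <- function(peptides, masks, to_missing = FALSE) {
  m <- as_alignment_matrix(peptides)
  if (!all(names(masks) %in% rownames(m)))
    stop("mask ids not present in the alignment: ",
         paste(setdiff(names(masks), rownames(m)), collapse = ", "))
  mark <- if (to_missing) "-" else "O"
  for (id in names(masks)) {
    idx <- masks[[id]]
    if (length(idx) == 0L) next
    if (any(idx < 1L | idx > ncol(m)))
      stop("mask for '", id, "' is out of range for an alignment of width ",
           ncol(m))
    keep <- m[id, idx] != "-"
    m[id, idx[keep]] <- mark
  }
  m
}

## CG restoration -------------------------------------------------------------

dinuc_counts <- function(left, right) {
  ok <- left != "-" & right != "-"
  di <- paste0(left[ok], right[ok])
  c(CG = sum(di == "CG"), TG = sum(di == "TG"), CA = sum(di == "CA"))
}

#' Restore a CG dinucleotide in one consensus codon
#'
#' Operates on one aligned codon column. If, at either within-codon
#' dinucleotide (positions 1-2 or 2-3), the column contains the CG form in at
#' least `min_cg` copies together with at least one decay product (TG or CA),
#' the consensus dinucleotide is set to CG regardless of plurality; otherwise
#' the base consensus is returned unchanged. Cross-codon junctions are
#' handled by [restore_cg_alignment_consensus()], which sees adjacent
#' columns.
#'
#' @param column_codons Character vector of 3-letter codons observed at one
#'   aligned codon position.
#' @param base_consensus The plurality consensus codon for the column.
#' @param min_cg Minimum number of CG observations required (default 1:
#'   presence, mirroring the permissive "populated by CG, and TG or CA").
#' @return Consensus codon (string of length 3).
#' @export
restore_cg_consensus <- function(column_codons, base_consensus, min_cg = 2L) {
  cod <- do.call(rbind, strsplit(toupper(column_codons), ""))
  if (ncol(cod) != 3L) stop("codons must have length 3")
  out <- strsplit(toupper(base_consensus), "")[[1]]
  for (p in c(1L, 2L)) {
    cnt <- dinuc_counts(cod[, p], cod[, p + 1L])
    if (cnt["CG"] >= min_cg && (cnt["TG"] > 0L || cnt["CA"] > 0L))
      out[p:(p + 1L)] <- c("C", "G")
  }
  paste0(out, collapse = "")
}

#' Plurality nucleotide consensus with optional CG restoration
#'
#' Builds a per-column plurality consensus of a nucleotide alignment (a
#' column is `"-"` when gaps are the absolute majority), then -- when
#' `restore_cg = TRUE` -- rewrites every adjacent position pair where the
#' alignment is populated by CG together with a decay product (TG or CA) to
#' CG. All three dinucleotide frames are considered (codon positions 1-2 and
#' 2-3, and the cross-codon junction), symmetric with the masking rule of
#' [cg_affected_positions()].
#'
#' @param codon_aln DNA alignment (matrix or named vector), in frame.
#' @param restore_cg Reinstate decayed CG dinucleotides.
#' @param min_cg Minimum CG observations required for restoration.
#' @return Consensus nucleotide string.
#' @export
nt_consensus <- function(codon_aln, restore_cg = TRUE, min_cg = 2L) {
  m <- as_alignment_matrix(codon_aln)
  validate_alphabet(m, "dna")
  L <- ncol(m)
  cons <- character(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    if (sum(col == "-") > length(col) / 2) { cons[j] <- "-"; next }
    obs <- col[col != "-"]
    tab <- sort(table(obs), decreasing = TRUE)
    cons[j] <- names(tab)[1L]
  }
  if (restore_cg && L > 1L) {
    for (j in seq_len(L - 1L)) {
      cnt <- dinuc_counts(m[, j], m[, j + 1L])
      if (cnt["CG"] >= min_cg && (cnt["TG"] > 0L || cnt["CA"] > 0L))
        cons[j:(j + 1L)] <- c("C", "G")
    }
  }
  paste0(cons, collapse = "")
}
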