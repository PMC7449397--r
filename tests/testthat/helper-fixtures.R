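# Shared helpers: tiny in-code fixtures and quiet wrappers.

quiet_mds <- function(...) suppressMessages(classical_mds(...))

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

# Two tight, well-separated peptide groups (identical within, 3 diffs between).
two_group_peptides <- function(n_per = 4L) {
  a <- "MKLAVGEWFYHD"
  b <- "MKLAVGEWTQHN"
  seqs <- c(rep(a, n_per), rep(b, n_per))
  names(seqs) <- paste0(rep(c("a", "b"), each = n_per), seq_len(n_per))
  as_alignment_matrix(seqs)
}

# Random peptide alignment over the 20 standard residues.
random_peptides <- function(n, L, seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(AA20, n * L, replace = TRUE), nrow = n)
  rownames(m) <- paste0("s", seq_len(n))
  m
}

# Random in-frame codon sequence without stops.
random_cds <- function(n_codons, seed = 1L) {
  set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
}
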