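## Distance-based trees over cluster consensus peptides.
##
## Neighbor-joining over difference matrices is used as the desk-scale tree
## stage; for external maximum-likelihood inference, export the consensus
## alignment with write_alignment() (FASTA) or write_phylip() and run your
## ML tool of choice on it.

#' Neighbor-joining tree over consensus records
#'
#' Standard neighbor-joining (as implemented in \pkg{ape}) on a difference
#' matrix, typically from [pairwise_difference()] on CG-null consensus
#' peptides so that decay-exposed positions count as missing data, not
#' divergence. Negative branch lengths (an NJ artifact on noisy matrices)
#' are clamped to zero with a message.
#'
#' @param D A `diff_matrix`, `dist` or symmetric matrix over >= 3 leaves.
#' @return An [ape::nj()] tree (`phylo`), unrooted.
#' @export
nj_tree <- function(D) {
  Dm <- as_dist_matrix(D)
  if (nrow(Dm) < 3L) stop("neighbor-joining needs at least 3 leaves")
  tr <- ape::nj(stats::as.dist(Dm))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Write a tree in Newick format
#'
#' Leaf labels containing whitespace are quoted so the file round-trips.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  needs_quote <- grepl("\\s", tree$tip.label)
  tree$tip.label[needs_quote] <-
    paste0("'", tree$tip.label[needs_quote], "'")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree written by [write_newick()]
#'
#' @param path Newick path.
#' @return A `phylo` tree with quoting stripped.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  quoted <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[quoted] <- gsub("_", " ",
                               gsub("^'|'$", "", tr$tip.label[quoted]),
                               fixed = FALSE)
  tr
}

#' Export an alignment in sequential PHYLIP format
#'
#' Convenience export for external maximum-likelihood tools.
#'
#' @param aln Alignment (matrix or named vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(aln, path) {
  m <- as_alignment_matrix(aln)
  ids <- gsub("\\s", "_", rownames(m))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(m), ncol(m)), con)
  writeLines(sprintf("%-12s%s", ids,
                     apply(m, 1L, paste0, collapse = "")), con)
  invisible(path)
}
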