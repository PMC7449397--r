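## One-hot principal component sequence space.
##
## Each residue of an aligned peptide is encoded as a unique 20-bit binary
## vector; gap, "O" and "X" positions encode as all-zero blocks, so missing
## data falls to the block centroid after mean-centering. PCA is plain
## mean-centered SVD with no column scaling: scaling binary indicator
## columns would inflate rare-residue noise. Two sequences differing at d
## fully observed positions sit at squared Euclidean distance 2d, which ties
## the PCA geometry to Hamming distance.

#' One-hot encode a peptide alignment
#'
#' @param peptides Protein alignment (matrix or named vector) over the
#'   extended alphabet.
#' @return Object of class `one_hot`: list with `matrix` (N x 20L binary),
#'   `row_ids`, and `column_map` (data.frame of position, residue per
#'   column).
#' @export
one_hot_encode <- function(peptides) {
  m <- as_alignment_matrix(peptides)
  validate_alphabet(m, "protein")
  L <- ncol(m)
  X <- matrix(0, nrow = nrow(m), ncol = 20L * L)
  for (j in seq_len(L)) {
    ri <- match(m[, j], AA20)       # NA for "-", "O", "X"
    ok <- !is.na(ri)
    X[cbind(which(ok), 20L * (j - 1L) + ri[ok])] <- 1
  }
  column_map <- data.frame(position = rep(seq_len(L), each = 20L),
                           residue = rep(AA20, times = L),
                           stringsAsFactors = FALSE)
  colnames(X) <- paste0("p", column_map$position, ".", column_map$residue)
  rownames(X) <- rownames(m)
  structure(list(matrix = X, row_ids = rownames(m), column_map = column_map),
            class = "one_hot")
}

as_onehot_matrix <- function(x) {
  if (inherits(x, "one_hot")) return(x$matrix)
  if (is.matrix(x) && is.numeric(x)) return(x)
  one_hot_encode(x)$matrix
}

#' Fit a principal-component sequence space
#'
#' Mean-centered SVD of the one-hot matrix (no column scaling). Component
#' signs are fixed so that the loading of largest magnitude on each
#' component is positive, making coordinates reproducible across platforms.
#'
#' @param onehot A `one_hot` object, a numeric matrix, or a peptide
#'   alignment (encoded on the fly).
#' @param k Number of components to retain (default 3, matching a
#'   three-dimensional view of the space); must satisfy
#'   `k <= min(N - 1, ncol)`.
#' @return Object of class `pca_space`: `center`, `loadings` (20L x k),
#'   `scores` (N x k), `explained` (variance fractions), `k`.
#' @export
fit_pca <- function(onehot, k = 3L) {
  X <- as_onehot_matrix(onehot)
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 sequences")
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, ncol(X)))
    stop("k must be between 1 and min(N - 1, ncol) = ",
         min(n - 1L, ncol(X)))
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = k, nv = k)
  # sign convention: largest-|loading| entry positive per component
  for (i in seq_len(k)) {
    pivot <- which.max(abs(sv$v[, i]))
    if (sv$v[pivot, i] < 0) {
      sv$v[, i] <- -sv$v[, i]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- sv$v
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- colnames(scores)
  structure(list(center = center, loadings = loadings, scores = scores,
                 explained = sv$d^2 / sum(sv$d^2), k = k),
            class = "pca_space")
}

#' @export
print.pca_space <- function(x, ...) {
  cat("<pca_space> ", nrow(x$scores), " sequences, k = ", x$k,
      "; explained: ",
      paste0(sprintf("%.1f%%", 100 * x$explained[seq_len(x$k)]),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project peptides into a fitted PCA space
#'
#' Centers with the training mean and multiplies by the component loadings.
#' Projecting a training sequence reproduces its fitted score exactly; the
#' map is affine, so variant sequences (e.g. engineered mosaics) can be
#' placed in the space of the natural families.
#'
#' @param space A `pca_space`.
#' @param peptides Peptide alignment over the same columns as the training
#'   alignment (or a `one_hot`/numeric matrix of matching width).
#' @return N' x k coordinate matrix.
#' @export
project_into_space <- function(space, peptides) {
  stopifnot(inherits(space, "pca_space"))
  X <- as_onehot_matrix(peptides)
  if (ncol(X) != length(space$center))
    stop("length mismatch: query encodes to ", ncol(X),
         " columns, training space has ", length(space$center))
  sweep(X, 2L, space$center) %*% space$loadings
}

#' Write ordination coordinates with labels as TSV
#'
#' @param coords Numeric coordinate matrix with rownames.
#' @param path Output path.
#' @param labels Optional named vector of group labels (e.g. family).
#' @return Invisibly, `path`.
#' @export
write_coordinates <- function(coords, path, labels = NULL) {
  df <- data.frame(id = rownames(coords), coords, check.names = FALSE)
  if (!is.null(labels)) df$label <- unname(labels[df$id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
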