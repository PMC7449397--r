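## Per-family difference-matrix metric MDS, K-means cluster retrieval,
## supplementary-point projection (Gower), and greedy identity clustering.
##
## Distances are raw per-pair difference counts over comparable columns:
## columns holding "-", "O" or "X" in either sequence of a pair are deleted
## pairwise, because CG-null positions are missing data, not differences.

informative_mask <- function(m) {
  matrix(m %in% AA20, nrow = nrow(m), dimnames = dimnames(m))
}

#' Pairwise difference matrix of aligned peptides
#'
#' `D[i, j]` is the number (or fraction) of columns where both sequences
#' carry standard residues and those residues differ. Columns with `"-"`,
#' `"O"` or `"X"` in either sequence are excluded pairwise; the number of
#' co-observed columns is returned alongside so that low-overlap pairs can
#' be flagged.
#'
#' @param peptides Protein alignment.
#' @param scale `"count"` (raw differences, the default) or `"proportion"`
#'   (differences / comparable columns, for unequal-coverage data).
#' @param min_overlap Pairs with fewer comparable columns are flagged.
#' @return Object of class `diff_matrix`: `D` (N x N), `comparable` (N x N
#'   co-observed column counts), `flagged` (data.frame of low-overlap
#'   pairs), `scale`.
#' @export
pairwise_difference <- function(peptides, scale = c("count", "proportion"),
                                min_overlap = 20L) {
  scale <- match.arg(scale)
  m <- as_alignment_matrix(peptides)
  X <- as_onehot_matrix(m)
  inf <- informative_mask(m) * 1
  matches <- tcrossprod(X)
  comparable <- tcrossprod(inf)
  D <- comparable - matches
  diag(D) <- 0
  off <- comparable == 0; diag(off) <- FALSE
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1L, ]
    stop("no comparable columns between '", rownames(m)[ij[1L]], "' and '",
         rownames(m)[ij[2L]], "'")
  }
  if (scale == "proportion") {
    D <- D / comparable
    diag(D) <- 0
  }
  dimnames(D) <- dimnames(comparable) <- list(rownames(m), rownames(m))
  low <- which(comparable < min_overlap & upper.tri(comparable),
               arr.ind = TRUE)
  flagged <- data.frame(id1 = rownames(m)[low[, 1L]],
                        id2 = rownames(m)[low[, 2L]],
                        comparable = comparable[low],
                        stringsAsFactors = FALSE)
  structure(list(D = D, comparable = comparable, flagged = flagged,
                 scale = scale),
            class = "diff_matrix")
}

#' Differences between query and training alignments
#'
#' Cross version of [pairwise_difference()]: distances from each query
#' sequence to every training sequence, over the same alignment columns.
#' Feed the result to [project_supplementary()].
#'
#' @param query,training Protein alignments with identical column count.
#' @inheritParams pairwise_difference
#' @return List with `D` (N_query x N_train) and `comparable`.
#' @export
cross_difference <- function(query, training,
                             scale = c("count", "proportion")) {
  scale <- match.arg(scale)
  q <- as_alignment_matrix(query)
  t_ <- as_alignment_matrix(training)
  if (ncol(q) != ncol(t_))
    stop("query and training alignments have different widths")
  Xq <- as_onehot_matrix(q); Xt <- as_onehot_matrix(t_)
  comparable <- tcrossprod(informative_mask(q) * 1, informative_mask(t_) * 1)
  if (any(comparable == 0))
    stop("a query/training pair has no comparable columns")
  D <- comparable - tcrossprod(Xq, Xt)
  if (scale == "proportion") D <- D / comparable
  dimnames(D) <- list(rownames(q), rownames(t_))
  list(D = D, comparable = comparable)
}

as_dist_matrix <- function(x) {
  if (inherits(x, "diff_matrix")) return(x$D)
  if (inherits(x, "dist")) return(as.matrix(x))
  as.matrix(x)
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared distance matrix (`B = -J D^2 J / 2`),
#' eigendecomposes, and returns the top-`m` positive-eigenvalue axes scaled
#' by the square root of their eigenvalues. Negative eigenvalues (present
#' when `D` is not Euclidean-embeddable) are dropped and their mass fraction
#' reported via `message()`. The training `B` diagonal and eigenvalues are
#' retained so that new sequences can be added by
#' [project_supplementary()].
#'
#' @param D A `diff_matrix`, `dist`, or symmetric zero-diagonal matrix.
#' @param m Target dimension (default 2, the usual graphical view).
#' @return Object of class `mds_space`: `coordinates` (N x m),
#'   `eigenvalues` (all, non-increasing), `b_diag`, `m`, `ids`.
#' @export
classical_mds <- function(D, m = 2L) {
  Dm <- as_dist_matrix(D)
  n <- nrow(Dm)
  if (n < 2L) stop("need at least 2 points")
  if (max(abs(Dm - t(Dm))) > 1e-8) stop("distance matrix is not symmetric")
  D2 <- Dm^2
  B <- -0.5 * (D2 - outer(rowMeans(D2), rep(1, n)) -
                 outer(rep(1, n), colMeans(D2)) + mean(D2))
  eg <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  npos <- sum(eg$values > tol)
  neg_mass <- sum(abs(eg$values[eg$values < -tol]))
  if (neg_mass > 0)
    message(sprintf("dropping negative eigenvalue mass: %.2f%% of spectrum",
                    100 * neg_mass / sum(abs(eg$values))))
  m <- as.integer(m)
  if (npos == 0L) {
    coords <- matrix(0, n, m)
  } else {
    if (m > npos) {
      warning("requested m = ", m, " exceeds positive-eigenvalue count ",
              npos, "; reduced")
      m <- npos
    }
    vec <- eg$vectors[, seq_len(m), drop = FALSE]
    for (i in seq_len(m)) {          # deterministic sign
      pivot <- which.max(abs(vec[, i]))
      if (vec[pivot, i] < 0) vec[, i] <- -vec[, i]
    }
    coords <- vec %*% diag(sqrt(eg$values[seq_len(m)]), nrow = m)
  }
  ids <- rownames(Dm) %||% paste0("seq", seq_len(n))
  dimnames(coords) <- list(ids, paste0("Dim", seq_len(ncol(coords))))
  structure(list(coordinates = coords, eigenvalues = eg$values,
                 b_diag = diag(B), m = ncol(coords), ids = ids),
            class = "mds_space")
}

#' @export
print.mds_space <- function(x, ...) {
  ev <- x$eigenvalues
  cat("<mds_space> ", length(x$ids), " points, m = ", x$m,
      "; top eigenvalue share: ",
      sprintf("%.1f%%", 100 * ev[1L] / sum(abs(ev))), "\n", sep = "")
  invisible(x)
}

#' Project supplementary points into an MDS space
#'
#' Gower's supplementary-point formula: for a new point with squared
#' distances `d^2` to the training points,
#' `x = (1/2) * Lambda^-1 * X' * (b_diag - d^2)`, where `X` holds the
#' training coordinates, `Lambda` the retained eigenvalues, and `b_diag`
#' the diagonal of the training double-centered matrix. Projecting a
#' training point reproduces its own coordinates.
#'
#' @param space An `mds_space`.
#' @param d_new Matrix of distances from each new sequence (rows) to all
#'   training sequences (columns), e.g. `cross_difference(...)$D`; a vector
#'   is treated as one point.
#' @return N' x m coordinate matrix.
#' @export
project_supplementary <- function(space, d_new) {
  stopifnot(inherits(space, "mds_space"))
  if (is.list(d_new) && !is.null(d_new$D)) d_new <- d_new$D
  if (is.null(dim(d_new))) d_new <- matrix(d_new, nrow = 1L)
  n <- length(space$ids)
  if (ncol(d_new) != n)
    stop("d_new must have one column per training sequence (", n, ")")
  lambda <- space$eigenvalues[seq_len(space$m)]
  keep <- lambda > 0
  X <- space$coordinates[, keep, drop = FALSE]
  coords <- matrix(0, nrow(d_new), space$m,
                   dimnames = list(rownames(d_new), colnames(space$coordinates)))
  centered <- sweep(-(d_new^2), 2L, -space$b_diag)  # b_diag - d^2, rowwise
  coords[, keep] <- 0.5 * centered %*% X %*% diag(1 / lambda[keep],
                                                  nrow = sum(keep))
  coords
}

## Cluster assignments --------------------------------------------------------

new_cluster_assignment <- function(labels, K, tags, family = NULL,
                                   centroids = NULL, selection_scores = NULL,
                                   method = "kmeans") {
  structure(list(labels = labels, K = K, tags = tags, family = family,
                 centroids = centroids, selection_scores = selection_scores,
                 method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " sequences in ", x$K,
      " cluster(s): ", paste(x$tags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' K-means cluster retrieval in MDS space
#'
#' Best-of-`restarts` K-means on the MDS coordinates, deterministic for a
#' given seed. Clusters are renumbered by decreasing size (ties broken by
#' centroid lexicographic order) and tagged `cLn.n` -- cluster number
#' followed by family number -- when `family` is supplied.
#'
#' @param space An `mds_space` (or bare coordinate matrix).
#' @param K Number of clusters, `1 <= K <= N`.
#' @param seed RNG seed.
#' @param restarts Number of random starts.
#' @param family Family number used in `cLn.n` tags.
#' @param selection_scores Optional per-K quality table from [select_k()].
#' @return A `cluster_assignment`.
#' @export
kmeans_cluster <- function(space, K, seed = 1L, restarts = 25L,
                           family = NULL, selection_scores = NULL) {
  coords <- if (inherits(space, "mds_space")) space$coordinates else space
  n <- nrow(coords)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("K must be between 1 and N = ", n)
  if (K == 1L) {
    labels <- stats::setNames(rep(1L, n), rownames(coords))
    centroids <- matrix(colMeans(coords), nrow = 1L,
                        dimnames = list(NULL, colnames(coords)))
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    km <- suppressWarnings(
      stats::kmeans(coords, centers = K, nstart = restarts, iter.max = 100L))
    labels <- stats::setNames(km$cluster, rownames(coords))
    centroids <- km$centers
  }
  # renumber by decreasing size, ties by centroid lexicographic order
  sizes <- tabulate(labels, nbins = K)
  ord <- order(-sizes, apply(centroids, 1L, function(r)
    paste(sprintf("%+.12e", r), collapse = ",")))
  relabel <- match(seq_len(K), ord)
  labels <- stats::setNames(relabel[labels], names(labels))
  centroids <- centroids[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  tags <- if (is.null(family)) paste0("cL", seq_len(K))
          else sprintf("cL%d.%d", seq_len(K), as.integer(family))
  new_cluster_assignment(labels, K, tags, family = family,
                         centroids = centroids,
                         selection_scores = selection_scores)
}

#' Choose K by mean silhouette
#'
#' Runs [kmeans_cluster()] for each candidate K and returns the K with the
#' highest mean silhouette width on the MDS coordinates. The full per-K
#' score table is attached as attribute `"scores"`; when the best silhouette
#' is weak (< 0.25) the result carries `attr(, "low_confidence") = TRUE`.
#' A degenerate space (all points identical) returns 1 with a warning.
#'
#' @param space An `mds_space`.
#' @param k_range Candidate K values (clipped to `[2, N - 1]`).
#' @param seed,restarts Passed to [kmeans_cluster()].
#' @return Integer K with attributes `scores` and `low_confidence`.
#' @export
select_k <- function(space, k_range = 2:8, seed = 1L, restarts = 25L) {
  coords <- if (inherits(space, "mds_space")) space$coordinates else space
  n <- nrow(coords)
  if (nrow(unique(coords)) == 1L) {
    warning("degenerate space: all points identical; returning K = 1")
    out <- 1L
    attr(out, "scores") <- stats::setNames(numeric(0), character(0))
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) stop("k_range is empty after clipping to [2, N-1]")
  dmat <- stats::dist(coords)
  scores <- vapply(k_range, function(k) {
    asg <- kmeans_cluster(coords, k, seed = seed, restarts = restarts)
    if (length(unique(asg$labels)) < 2L) return(NA_real_)
    sil <- cluster::silhouette(unname(asg$labels), dmat)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(scores) <- paste0("K", k_range)
  best <- k_range[which.max(scores)]
  out <- best
  attr(out, "scores") <- scores
  attr(out, "low_confidence") <- max(scores, na.rm = TRUE) < 0.25
  out
}

#' Greedy identity sub-clustering
#'
#' Greedy centroid clustering in the style of sequence dereplication tools:
#' sequences are processed in input order; each joins the first existing
#' centroid whose identity over comparable columns is at least `id`,
#' otherwise it founds a new centroid. With `id = 1` this probes a set for
#' emerging sub-clusters that are minimally divergent from their consensus.
#'
#' @param peptides Protein alignment.
#' @param id Identity threshold in (0, 1].
#' @param family Optional family number for tags.
#' @return A `cluster_assignment` (clusters numbered in founding order;
#'   `centroids` holds the founder sequence ids).
#' @export
greedy_identity_cluster <- function(peptides, id = 1.0, family = NULL) {
  stopifnot(id > 0, id <= 1)
  m <- as_alignment_matrix(peptides)
  inf <- informative_mask(m)
  founders <- integer(0)
  labels <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    placed <- FALSE
    for (ci in seq_along(founders)) {
      f <- founders[ci]
      comp <- inf[i, ] & inf[f, ]
      nc <- sum(comp)
      if (nc == 0L) next
      ident <- sum(m[i, comp] == m[f, comp]) / nc
      if (ident >= id) { labels[i] <- ci; placed <- TRUE; break }
    }
    if (!placed) { founders <- c(founders, i); labels[i] <- length(founders) }
  }
  K <- length(founders)
  tags <- if (is.null(family)) paste0("c", seq_len(K))
          else sprintf("c%d.%d", seq_len(K), as.integer(family))
  new_cluster_assignment(stats::setNames(labels, rownames(m)), K, tags,
                         family = family,
                         centroids = rownames(m)[founders],
                         method = "greedy_identity")
}

## Space serialization --------------------------------------------------------

#' Serialize an MDS space to JSON
#'
#' Versioned JSON with training ids, coordinates, eigenvalues and the `B`
#' diagonal -- everything [project_supplementary()] needs.
#'
#' @param space An `mds_space`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mds_space <- function(space, path) {
  stopifnot(inherits(space, "mds_space"))
  obj <- list(format = "ccspace.mds_space", version = 1L,
              ids = space$ids, m = space$m,
              coordinates = unname(as.matrix(space$coordinates)),
              eigenvalues = space$eigenvalues, b_diag = unname(space$b_diag))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an MDS space serialized by [write_mds_space()]
#'
#' @param path JSON path.
#' @return An `mds_space`.
#' @export
read_mds_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ccspace.mds_space"))
    stop("'", path, "' is not a serialized mds_space")
  coords <- matrix(obj$coordinates, nrow = length(obj$ids))
  dimnames(coords) <- list(obj$ids, paste0("Dim", seq_len(ncol(coords))))
  structure(list(coordinates = coords, eigenvalues = obj$eigenvalues,
                 b_diag = obj$b_diag, m = obj$m, ids = obj$ids),
            class = "mds_space")
}
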