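test_that("pairwise differences use pairwise deletion of missing data", {
  aln <- as_alignment_matrix(c(a = "AAAA", b = "AAAT", c = "AOAA",
                               d = "ATAT"))
  dm <- pairwise_difference(aln, min_overlap = 3L)
  expect_equal(unname(dm$D["a", "a"]), 0)
  expect_equal(unname(dm$D["a", "b"]), 1)
  expect_equal(unname(dm$D["c", "d"]), 1)          # comparable {1,3,4}
  expect_equal(unname(dm$comparable["c", "d"]), 3)
  expect_true(all(dm$D == t(dm$D)))
  prop <- pairwise_difference(aln, scale = "proportion", min_overlap = 3L)
  expect_equal(unname(prop$D["a", "b"]), 0.25)
  # low-overlap pairs are flagged
  dm2 <- pairwise_difference(aln, min_overlap = 4L)
  expect_true(nrow(dm2$flagged) > 0)
  # a pair with no comparable columns is an error naming the pair
  bad <- as_alignment_matrix(c(x = "AO", y = "OA"))
  expect_error(pairwise_difference(bad), "no comparable columns.*'[xy]'")
})

test_that("classical MDS recovers Euclidean geometry exactly", {
  # three collinear points
  D3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  sp3 <- quiet_mds(D3, m = 1)
  expect_equal(sort(as.vector(stats::dist(sp3$coordinates))), c(1, 1, 2),
               tolerance = 1e-10)
  # random 2-D point cloud reproduced to 1e-8
  set.seed(8)
  pts <- matrix(rnorm(60), ncol = 2)
  D <- as.matrix(stats::dist(pts))
  sp <- quiet_mds(D, m = 2)
  expect_lt(max(abs(as.matrix(stats::dist(sp$coordinates)) - D)), 1e-8)
  # eigenvalues sorted, coordinates only on positive axes
  expect_true(all(diff(sp$eigenvalues) < 1e-9))
  # independent oracle: stats::cmdscale spans the same configuration
  cm <- stats::cmdscale(D, k = 2)
  expect_lt(max(abs(as.matrix(stats::dist(cm)) -
                      as.matrix(stats::dist(sp$coordinates)))), 1e-8)
  # identical sequences collapse to the origin
  same <- as_alignment_matrix(c(a = "MKL", b = "MKL", c = "MKL"))
  sp0 <- quiet_mds(pairwise_difference(same, min_overlap = 1L), m = 2)
  expect_lt(max(abs(sp0$coordinates)), 1e-10)
  # m beyond the positive spectrum is reduced with a warning
  expect_warning(quiet_mds(D3, m = 3), "reduced")
})

test_that("supplementary projection reproduces training points and symmetry", {
  set.seed(5)
  pts <- matrix(rnorm(40), ncol = 2)
  D <- as.matrix(stats::dist(pts))
  sp <- quiet_mds(D, m = 2)
  expect_lt(max(abs(project_supplementary(sp, D) - sp$coordinates)), 1e-8)
  # a point equidistant from two mirror-image clusters lands on the axis
  train <- rbind(c(-2, 1), c(-2, -1), c(2, 1), c(2, -1))
  Dt <- as.matrix(stats::dist(train))
  spt <- quiet_mds(Dt, m = 2)
  mid <- sqrt(rowSums(sweep(train, 2, c(0, 0))^2))
  proj <- project_supplementary(spt, matrix(mid, nrow = 1))
  # Dim1 carries the left/right split; the midpoint must not lean either way
  expect_lt(abs(proj[1, 1]), 1e-8)
})

test_that("K-means retrieves planted lineages and is deterministic by seed", {
  sim <- simulate_family_series(
    sim_params(n_families = 1, lineages_per_family = 2,
               copies_per_lineage = 25, seed = 13))
  pep <- cg_null_translate_alignment(sim$families$F1$codon_aln)
  sp <- quiet_mds(pairwise_difference(pep), m = 2)
  asg <- kmeans_cluster(sp, 2, seed = 1, family = 1)
  expect_equal(truth_metrics(asg, sim, 1)$ari, 1)
  asg2 <- kmeans_cluster(sp, 2, seed = 1, family = 1)
  expect_identical(asg$labels, asg2$labels)
  # tags numbered by decreasing size
  expect_equal(asg$tags, c("cL1.1", "cL2.1"))
  sizes <- table(asg$labels)
  expect_true(all(diff(as.integer(sizes)) <= 0))
  # K = 1 and duplicate points
  one <- kmeans_cluster(sp, 1)
  expect_equal(unname(unique(one$labels)), 1L)
  dup <- matrix(c(0, 0, 0, 0, 5, 5), ncol = 2, byrow = TRUE,
                dimnames = list(c("p", "q", "r"), NULL))
  asg3 <- kmeans_cluster(dup, 2, seed = 1)
  expect_equal(asg3$labels[["p"]], asg3$labels[["q"]])
  expect_error(kmeans_cluster(sp, 100), "K must be")
})

test_that("silhouette-based selection finds the planted cluster number", {
  sim <- simulate_family_series(
    sim_params(n_families = 1, lineages_per_family = 3,
               copies_per_lineage = 17, seed = 19))
  pep <- cg_null_translate_alignment(sim$families$F1$codon_aln)
  sp <- quiet_mds(pairwise_difference(pep), m = 2)
  K <- select_k(sp, seed = 1)
  expect_equal(as.integer(K), 3L)
  expect_named(attr(K, "scores"), paste0("K", 2:8))
  expect_false(attr(K, "low_confidence"))
  # unequal cluster sizes (80/20)
  set.seed(2)
  coords <- rbind(matrix(rnorm(160, 0, 0.3), ncol = 2),
                  matrix(rnorm(40, 6, 0.3), ncol = 2))
  rownames(coords) <- paste0("s", 1:100)
  sp2 <- quiet_mds(as.matrix(stats::dist(coords)), m = 2)
  expect_equal(as.integer(select_k(sp2, seed = 1)), 2L)
  # degenerate space
  same <- as_alignment_matrix(c(a = "MKL", b = "MKL", c = "MKL"))
  sp0 <- quiet_mds(pairwise_difference(same, min_overlap = 1L), m = 2)
  expect_warning(K0 <- select_k(sp0), "degenerate")
  expect_equal(as.integer(K0), 1L)
})

test_that("greedy identity clustering matches exhaustive order enumeration", {
  aln <- two_group_peptides(2L)
  g <- greedy_identity_cluster(aln, id = 1.0)
  expect_equal(g$K, 2L)
  expect_equal(unname(g$labels), c(1L, 1L, 2L, 2L))
  # all-identical set
  same <- as_alignment_matrix(c(a = "MKL", b = "MKL"))
  expect_equal(greedy_identity_cluster(same, 1.0)$K, 1L)
  # one comparable difference splits at id = 1.0
  pair <- as_alignment_matrix(c(a = "MKLF", b = "MKLT"))
  expect_equal(greedy_identity_cluster(pair, 1.0)$K, 2L)
  # separated data: cluster count invariant under processing order
  base <- two_group_peptides(3L)
  counts <- vapply(1:20, function(i) {
    set.seed(i)
    greedy_identity_cluster(base[sample(nrow(base)), ], id = 1.0)$K
  }, integer(1))
  expect_true(all(counts == 2L))
  # missing data only reduces the comparable denominator
  part <- as_alignment_matrix(c(a = "MKOF", b = "MKXF"))
  expect_equal(greedy_identity_cluster(part, 1.0)$K, 1L)
})

test_that("MDS spaces serialize to JSON and back", {
  set.seed(3)
  D <- as.matrix(stats::dist(matrix(rnorm(30), ncol = 2)))
  sp <- quiet_mds(D, m = 2)
  path <- tempfile(fileext = ".json")
  write_mds_space(sp, path)
  sp2 <- read_mds_space(path)
  expect_equal(sp2$coordinates, sp$coordinates, tolerance = 1e-12)
  expect_equal(sp2$eigenvalues, sp$eigenvalues, tolerance = 1e-12)
  # a restored space still projects training points onto themselves
  expect_lt(max(abs(project_supplementary(sp2, D) - sp$coordinates)), 1e-8)
})
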