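test_that("simulations are reproducible and validated", {
  p <- sim_params(n_families = 2, copies_per_lineage = 5, seed = 4)
  s1 <- simulate_family_series(p)
  s2 <- simulate_family_series(p)
  expect_identical(s1, s2)
  expect_error(sim_params(n_families = 2, copies_per_lineage = 5),
               "seed is mandatory")
  expect_error(sim_params(cpg_rate_multiplier = 0.5, seed = 1), ">= 1")
  expect_error(sim_params(cc_region = c(50, 200), seed = 1), "cc_region")
  expect_error(sim_params(lineage_persistence = 1.5, seed = 1), "persistence")
  # every copy maps to exactly one lineage and family
  lab <- s1$truth$labels
  expect_equal(nrow(lab), 2L * 3L * 5L)
  expect_false(anyDuplicated(lab$id) > 0)
})

test_that("CpG survival follows the exponential decay expectation", {
  count_survival <- function(mult, age_scale, seed) {
    p <- sim_params(n_families = 1, lineages_per_family = 1,
                    copies_per_lineage = 200, cpg_rate_multiplier = mult,
                    neutral_rate = 0.008, decay_time_scale = age_scale,
                    seed = seed)
    sim <- simulate_family_series(p)
    aln <- sim$families$F1$codon_aln
    sites <- sim$truth$cpg_sites$F1$L1
    surv <- vapply(sites, function(s)
      sum(aln[, s] == "C" & aln[, s + 1] == "G"), numeric(1))
    list(k = sum(surv), n = length(sites) * 200L,
         expected = exp(-0.008 * mult * p$decay_time_scale))
  }
  # multiplier 1: CpG sites decay at the background rate
  r1 <- count_survival(1, 5, seed = 31)
  expect_gt(r1$n, 500L)
  ci1 <- stats::binom.test(r1$k, r1$n, r1$expected)$conf.int
  expect_true(r1$expected >= ci1[1] && r1$expected <= ci1[2])
  # multiplier 10 at an age giving 30% expected survival
  r2 <- count_survival(10, -log(0.3) / 0.08, seed = 32)
  ci2 <- stats::binom.test(r2$k, r2$n, 0.30)$conf.int
  expect_true(0.30 >= ci2[1] && 0.30 <= ci2[2])
})

test_that("decay is post-insertion only and increases with planted age", {
  sim <- simulate_family_series(sim_params(n_families = 3,
                                           copies_per_lineage = 30,
                                           seed = 17))
  # founders keep their planted CpGs
  for (fam in names(sim$truth$founders))
    for (l in names(sim$truth$founders[[fam]])) {
      nt <- strsplit(sim$truth$founders[[fam]][[l]]$nt, "")[[1]]
      sites <- sim$truth$cpg_sites[[fam]][[l]]
      expect_true(all(nt[sites] == "C" & nt[sites + 1L] == "G"))
    }
  # per-family CpG survival decreases with age (family 1 is oldest)
  surv_of <- function(fam) {
    aln <- sim$families[[fam]]$codon_aln
    lab <- sim$truth$labels[sim$truth$labels$family ==
                              sim$families[[fam]]$family, ]
    vals <- unlist(lapply(seq_along(sim$truth$cpg_sites[[fam]]), function(l) {
      ids <- lab$id[lab$lineage == l]
      sites <- sim$truth$cpg_sites[[fam]][[l]]
      vapply(sites, function(s)
        mean(aln[ids, s] == "C" & aln[ids, s + 1] == "G"), numeric(1))
    }))
    mean(vals)
  }
  s <- vapply(names(sim$families), surv_of, numeric(1))
  expect_true(s[["F1"]] < s[["F2"]] && s[["F2"]] < s[["F3"]])
})

test_that("masking lowers column diversity at planted CpG positions", {
  sim <- simulate_family_series(sim_params(n_families = 1, seed = 23))
  aln <- sim$families$F1$codon_aln
  plain <- suppressWarnings(as_alignment_matrix(vapply(
    rownames(aln), function(id)
      translate_codons(paste0(aln[id, ], collapse = "")), character(1))))
  masked <- cg_null_translate_alignment(aln)
  cpg_nt <- sort(unique(unlist(sim$truth$cpg_sites$F1)))
  cpg_codons <- sort(unique(ceiling(c(cpg_nt, cpg_nt + 1L) / 3)))
  diversity <- function(m, cols) {
    mean(vapply(cols, function(j) {
      obs <- m[, j][m[, j] %in% AA20]
      if (length(obs) == 0) 0 else 1 - max(table(obs)) / length(obs)
    }, numeric(1)))
  }
  div_before <- diversity(plain, cpg_codons)
  div_after <- diversity(masked, cpg_codons)
  expect_gt(div_before, div_after)
  # and before masking, CpG columns are noisier than untouched columns
  other <- setdiff(seq_len(ncol(masked)), cg_affected_columns(aln))
  expect_gt(div_before, diversity(plain, other))
})

test_that("truth metrics score assignments against planted lineages", {
  sim <- simulate_family_series(sim_params(n_families = 1, seed = 29))
  pep <- cg_null_translate_alignment(sim$families$F1$codon_aln)
  sp <- quiet_mds(pairwise_difference(pep), m = 2)
  asg <- kmeans_cluster(sp, 3, seed = 1, family = 1)
  expect_equal(truth_metrics(asg, sim, 1)$ari, 1)
  # random labels are chance-level over replicates
  aris <- vapply(1:20, function(i) {
    rnd <- asg
    set.seed(i)
    rnd$labels <- setNames(sample(rnd$labels), names(rnd$labels))
    truth_metrics(rnd, sim, 1)$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.1)
  # id mismatch is an error
  half <- asg
  half$labels <- half$labels[1:10]
  expect_error(truth_metrics(half, sim, 1), "ids do not match")
})

test_that("persistent lineages reappear unchanged in the next family", {
  sim <- simulate_family_series(
    sim_params(n_families = 3, lineage_persistence = 0.34,
               copies_per_lineage = 5, seed = 41))
  f <- sim$truth$founders
  expect_equal(f$F2$L1$nt, f$F1$L1$nt)
  expect_equal(f$F3$L1$nt, f$F1$L1$nt)
  expect_equal(f$F2$L1$origin, "F1_L1")
  expect_false(f$F2$L2$nt == f$F1$L2$nt)
})

test_that("simulation output directories contain alignments, truth and params", {
  sim <- simulate_family_series(sim_params(n_families = 1,
                                           copies_per_lineage = 3, seed = 2))
  dir <- file.path(tempfile(), "sim")
  write_sim(sim, dir)
  expect_true(file.exists(file.path(dir, "F1_codon.fasta")))
  aln <- read_alignment(file.path(dir, "F1_codon.fasta"), "dna")
  expect_equal(aln, sim$families$F1$codon_aln)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t")
  expect_equal(nrow(truth), 9L)
  expect_equal(yaml::read_yaml(file.path(dir, "params.yaml"))$seed, 2L)
})
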