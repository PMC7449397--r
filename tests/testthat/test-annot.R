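ref <- orf1_synthetic_reference()

test_that("heptad register is consistent and round-trips", {
  reg <- ref$register
  expect_equal(nrow(reg), 101L)                   # 14 x 7 + 3-residue stammer
  expect_equal(sum(reg$letter == "stm"), 3L)
  expect_equal(unique(reg$heptad[reg$letter == "stm"]), 6L)
  # landmark memberships
  expect_true(all(heptad_of(reg, c(105, 107, 108, 111)) %in% 8:9))
  expect_true(heptad_of(reg, 77) %in% 1:8)
  expect_true(!is.na(heptad_of(reg, 134)))        # F134 lies inside the coil
  # inverse maps
  for (h in c(1L, 6L, 14L))
    expect_true(all(heptad_of(reg, positions_of(reg, h)) == h))
  expect_true(is.na(heptad_of(reg, 1)))
  # simple two-heptad register
  reg2 <- assign_register(coiled_coil_annotation(1, 14, n_heptads = 2,
                                                 stammer_heptad = NULL))
  expect_equal(reg2$letter, rep(letters[1:7], 2))
  expect_error(coiled_coil_annotation(1, 20, n_heptads = 2,
                                      stammer_heptad = NULL),
               "inconsistent spans")
})

test_that("parent difference accounting matches the study design", {
  cc <- ref$regions$cc
  d_all <- diff_positions(ref$modern, ref$ancestral)
  expect_equal(nrow(d_all), 42L)
  expect_equal(nrow(diff_positions(ref$modern, ref$ancestral, cc)), 30L)
  d89 <- diff_positions(ref$modern, ref$ancestral,
                        positions_of(ref$register, 8:9))
  expect_equal(d89$position, c(105L, 107L, 108L, 111L))
  expect_equal(nrow(diff_positions(ref$modern, ref$modern)), 0L)
  # symmetry with swapped residue columns
  d_rev <- diff_positions(ref$ancestral, ref$modern)
  expect_equal(d_rev$position, d_all$position)
  expect_equal(d_rev$a, d_all$b)
  expect_error(diff_positions("MK", "MKL"), "length mismatch")
})

test_that("mosaic variants carry the documented ancestral residue counts", {
  cc <- ref$regions$cc
  v <- function(n) ref$variants$sequence[ref$variants$name == n]
  expect_equal(ancestral_residue_count(v("511"), ref$modern, ref$ancestral, cc), 21L)
  expect_equal(ancestral_residue_count(v("151"), ref$modern, ref$ancestral, cc), 9L)
  expect_equal(ancestral_residue_count(v("111"), ref$modern, ref$ancestral, cc), 0L)
  d51 <- diff_positions(v("151"), v("551"))
  expect_equal(nrow(d51), 25L)
  expect_equal(nrow(diff_positions(v("151"), v("551"), cc)), 21L)
  expect_equal(ancestral_residue_count(v("m39b"), ref$modern, ref$ancestral,
                                       positions_of(ref$register, 1:8)), 18L)
  # m39 lacks only the epistatic I77L
  d_m39 <- diff_positions(v("m39"), v("m39b"))
  expect_equal(d_m39$position, 77L)
  # modern + ancestral counts partition the parent differences
  for (nm in c("151", "511", "551", "555")) {
    am <- ancestral_residue_count(v(nm), ref$modern, ref$ancestral, cc)
    mm <- modern_residue_count(v(nm), ref$modern, ref$ancestral, cc)
    expect_equal(am + mm, 30L)
  }
})

test_that("activity classification follows the assay thresholds", {
  expect_equal(classify_activity(100), "active")
  expect_equal(classify_activity(80), "active")
  expect_equal(classify_activity(3), "inactive")
  expect_equal(classify_activity(50), "intermediate")
  expect_equal(classify_activity(c(95, 2, 40)),
               c("active", "inactive", "intermediate"))
  expect_error(classify_activity(-1), ">= 0")
  # fixture variants: fully ancestral/modern proteins active, 151 inactive
  act <- setNames(ref$variants$activity_class, ref$variants$name)
  expect_equal(unname(act[c("111", "555", "151", "m39b", "m39")]),
               c("active", "active", "inactive", "active", "inactive"))
})

test_that("column profiles flag hypervariable sites", {
  col <- matrix(c(rep("F", 90), rep("V", 6), rep("S", 3), "L"), ncol = 1)
  rownames(col) <- paste0("s", 1:100)
  prof <- column_profile(col, 1)
  expect_equal(prof$non_consensus, 0.10)
  expect_true(prof$flagged)
  inv <- column_profile(matrix(rep("F", 10), ncol = 1,
                               dimnames = list(paste0("s", 1:10))), 1)
  expect_equal(inv$non_consensus, 0)
  expect_false(inv$flagged)
  expect_error(column_profile(col, 2), "outside")
})

test_that("a planted hypervariable site is recovered within binomial error", {
  set.seed(99)
  n <- 400L; rate <- 0.10
  residues <- ifelse(runif(n) < rate, sample(c("V", "S"), n, TRUE), "F")
  col <- matrix(residues, ncol = 1, dimnames = list(paste0("s", 1:n)))
  prof <- column_profile(col, 1)
  ci <- stats::binom.test(round(prof$non_consensus * n), n)$conf.int
  expect_true(rate >= ci[1] && rate <= ci[2])
  expect_true(prof$flagged)
})

test_that("mosaic assembly validates composition and substitutions", {
  comp <- data.frame(start = c(1, 3), end = c(2, 4),
                     parent = c("modern", "ancestral"))
  expect_equal(build_mosaic("MKLF", "MVST", comp), "MKST")
  expect_equal(build_mosaic("MKLF", "MVST", comp, "S3W"), "MKWT")
  expect_error(build_mosaic("MKLF", "MVST", comp, "L3W"),
               "does not match")
  gap_comp <- data.frame(start = 1, end = 3, parent = "modern")
  expect_error(build_mosaic("MKLF", "MVST", gap_comp), "tile")
})
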