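test_that("CG-affected codon patterns are detected", {
  expect_equal(cg_affected_positions("CGA"), 1L)           # CGN
  expect_equal(cg_affected_positions("ACG"), 1L)           # NCG
  expect_equal(cg_affected_positions("TTCGGA"), c(1L, 2L)) # NNC|GNN, both
  expect_equal(cg_affected_positions("TTTAAA"), integer(0))
  # junction masking is configurable
  expect_equal(cg_affected_positions("TTCGGA", junction_mask = "left"), 1L)
  expect_equal(cg_affected_positions("TTCGGA", junction_mask = "right"), 2L)
  # gap codons break junctions and are never affected
  expect_equal(cg_affected_positions("TTC---GGA"), integer(0))
  expect_error(cg_affected_positions("CGAA"), "out-of-frame")
})

test_that("CG-null translation nulls affected residues only", {
  expect_equal(cg_null_translate("CGACGT"), "OO")
  expect_equal(cg_null_translate("ATGTTT"), "MF")
  expect_equal(cg_null_translate("TTCGAA"), "OO")
  expect_equal(cg_null_translate("ATG---TTT"), "M-F")
  expect_error(cg_null_translate("ATGT--TTT"), "partial gap")
})

test_that("internal stops translate to X with a warning", {
  expect_warning(aa <- translate_codons("ATGTAATTT"), "stop")
  expect_equal(aa, "MXF")
})

test_that("CG-null translation agrees with plain translation off the mask", {
  for (seed in 1:5) {
    s <- random_cds(40, seed = seed)
    plain <- strsplit(suppressWarnings(translate_codons(s)), "")[[1]]
    nulled <- strsplit(suppressWarnings(cg_null_translate(s)), "")[[1]]
    idx <- cg_affected_positions(s)
    expect_true(all(nulled[idx] == "O"))
    expect_equal(nulled[-idx], plain[-idx])
  }
})

test_that("peptide masks respect gaps and support missing-data conversion", {
  pep <- as_alignment_matrix(c(a = "MKLF", b = "MK-F"))
  masked <- apply_mask_to_peptides(pep, list(a = 3L, b = 3L))
  expect_equal(alignment_strings(masked), c(a = "MKOF", b = "MK-F"))
  expect_equal(apply_mask_to_peptides(pep, list(a = integer(0))), pep)
  to_na <- apply_mask_to_peptides(pep, list(a = 3L), to_missing = TRUE)
  expect_equal(alignment_strings(to_na)[["a"]], "MK-F")
  expect_error(apply_mask_to_peptides(pep, list(zz = 1L)), "zz")
})

test_that("CG restoration requires CG evidence plus a decay product", {
  expect_equal(restore_cg_consensus(
    c(rep("CGT", 3), rep("TGT", 4), rep("CAT", 3)), "TGT"), "CGT")
  expect_equal(restore_cg_consensus(rep("TGT", 10), "TGT"), "TGT")
  expect_equal(restore_cg_consensus(
    c(rep("CGT", 6), rep("TGT", 4)), "CGT"), "CGT")
  # a single chance CG observation is not treated as evidence by default
  expect_equal(restore_cg_consensus(
    c("CGT", rep("TGT", 9)), "TGT"), "TGT")
  expect_equal(restore_cg_consensus(
    c("CGT", rep("TGT", 9)), "TGT", min_cg = 1L), "CGT")
})

test_that("nucleotide consensus restores CG across all dinucleotide frames", {
  # NCG frame (codon positions 2-3): decay product is the plurality,
  # yet the CG form is reinstated
  aln <- c(a = "ACGTTT", b = "ACGTTT", c = "ATGTTT", d = "ATGTTT",
           e = "ATGTTT")
  expect_equal(substr(nt_consensus(aln, restore_cg = FALSE), 1, 3), "ATG")
  expect_equal(substr(nt_consensus(aln), 1, 3), "ACG")
  # cross-codon junction: ..C | G..
  aln2 <- c(a = "TTCGGG", b = "TTCGGG", c = "TTTGGG", d = "TTCAGG")
  expect_equal(nt_consensus(aln2), "TTCGGG")
  expect_equal(nt_consensus(aln2, restore_cg = FALSE), "TTCGGG")
  # no restoration without decay products; plurality rules
  aln3 <- c(a = "TGTTTT", b = "TGTTTT", c = "TGTTTT")
  expect_equal(nt_consensus(aln3), "TGTTTT")
})

test_that("column-level masks derive from the restored family consensus", {
  # founder codon CGT decayed in most copies; column still masked family-wide
  aln <- c(a = "CGTAAA", b = "TGTAAA", c = "CATAAA", d = "TGTAAA",
           e = "CGTAAA")
  cols <- cg_affected_columns(aln)
  expect_equal(cols, 1L)
  pep <- cg_null_translate_alignment(aln)
  expect_true(all(pep[, 1] == "O"))
  expect_true(all(pep[, 2] == "K"))
  # per-record masking nulls only copies that retain the CG form
  pep_rec <- cg_null_translate_alignment(aln, per = "record")
  expect_equal(unname(pep_rec[, 1]),
               c("O", "C", "H", "C", "O"))
})
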