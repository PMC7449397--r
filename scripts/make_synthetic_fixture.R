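#!/usr/bin/env Rscript
# Generates the synthetic ORF1p reference fixture under inst/extdata/.
# Run once from the repository root; outputs are committed. The fixture is a
# SYNTHETIC modern/ancestral parent pair whose difference structure follows
# the documented mosaic-variant study design; see R/orf1_fixture.R.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
L <- 338L
set.seed(20200814L)

modern <- sample(AA20, L, replace = TRUE)
# fixed landmark residues
modern[77] <- "I"
modern[105] <- "R"; modern[107] <- "L"; modern[108] <- "R"; modern[111] <- "C"
modern[134] <- "F"   # conserved non-CG-encoded F, hypervariable in young copies

# Coil spans 46-146: heptads 1-8 = 46..104, heptad 9 = 105..111 (quartet),
# h10 = 112..118, h12 = 126..132, h13 = 133..139; stammer inside heptad 6.
ntd_diffs <- c(9L, 14L, 27L, 33L)
cc_r1_diffs <- c(47L, 49L, 53L, 55L, 56L, 58L, 60L, 61L, 63L, 66L, 67L,
                 70L, 73L, 77L, 80L, 84L, 88L, 90L, 93L, 95L, 97L) # 21, h1-7
quartet <- c(105L, 107L, 108L, 111L)             # heptad 9
downstream5 <- c(113L, 116L, 127L, 130L, 136L)   # heptads 10, 12, 13
cterm_diffs <- c(160L, 175L, 190L, 210L, 240L, 270L, 300L, 320L)
all_diffs <- sort(c(ntd_diffs, cc_r1_diffs, quartet, downstream5, cterm_diffs))
stopifnot(length(all_diffs) == 42L, !anyDuplicated(all_diffs))

ancestral <- modern
for (p in all_diffs) ancestral[p] <- sample(setdiff(AA20, modern[p]), 1L)
ancestral[77] <- "L"
ancestral[105] <- "T"; ancestral[107] <- "F"
ancestral[108] <- "S"; ancestral[111] <- "F"

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(c(">modern_111p synthetic modern ORF1p parent",
             paste0(modern, collapse = ""),
             ">ancestral_555p synthetic resuscitated ancestral ORF1p parent",
             paste0(ancestral, collapse = "")),
           "inst/extdata/synthetic_orf1_parents.fasta")

writeLines(c(
  "# Synthetic ORF1p coiled coil annotation (residue coordinates, 1-based).",
  "cc_start: 46",
  "cc_end: 146",
  "n_heptads: 14",
  "stammer_heptad: 6",
  "regions:",
  "  region1: [1, 104]",
  "  region2: [105, 152]",
  "  region3: [153, 338]",
  "  cc: [46, 146]",
  "  ntd: [1, 45]",
  "  cterm: [147, 338]"),
  "inst/extdata/synthetic_orf1_annotation.yaml")

sub_str <- function(pos, from_seq, to_seq)
  paste0(from_seq[pos], pos, to_seq[pos], collapse = ";")

m39b_pos <- setdiff(cc_r1_diffs, c(93L, 95L, 97L))      # 18 incl. 77
m39_pos  <- setdiff(m39b_pos, 77L)                      # 17, no I77L
cc30_pos <- sort(c(cc_r1_diffs, quartet, downstream5))  # all 30 cc diffs

variants <- data.frame(
  name = c("111", "555", "551", "511", "151", "41b", "m39b", "m39",
           "151y", "m14", "m9", "R105T", "L107F", "R108S", "C111F", "m28c"),
  composition = c(
    "modern,modern,modern",        # 111
    "ancestral,ancestral,ancestral", # 555
    "ancestral,ancestral,modern",  # 551
    "ancestral,modern,modern",     # 511
    "modern,ancestral,modern",     # 151
    "modern,modern,modern",        # 41b: fully ancestral coil via subs
    "modern,ancestral,modern",     # m39b
    "modern,ancestral,modern",     # m39
    "modern,ancestral,modern",     # 151y
    "modern,modern,modern",        # m14
    "modern,modern,modern",        # m9
    "modern,modern,modern", "modern,modern,modern",
    "modern,modern,modern", "modern,modern,modern",
    "modern,ancestral,modern"),    # m28c
  substitutions = c(
    "", "", "", "", "",
    sub_str(cc30_pos, modern, ancestral),
    sub_str(m39b_pos, modern, ancestral),
    sub_str(m39_pos, modern, ancestral),
    "I77L",
    sub_str(downstream5, modern, ancestral),
    paste(c("C111F", strsplit(sub_str(downstream5, modern, ancestral),
                              ";")[[1]]), collapse = ";"),
    "R105T", "L107F", "R108S", "C111F",
    sub_str(ntd_diffs, modern, ancestral)),
  activity_pct = c(100, 85, 90, 90, 2, 50, 95, 2, 2, 90, 2, 2, 3, 2, 3, 2),
  expression_tested = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                        TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE
)
write.table(variants, "inst/extdata/synthetic_variants.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixture written to inst/extdata/\n")
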