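## Synthetic ORF1p reference pair.
##
## The package ships a SYNTHETIC modern/ancestral ORF1p parent pair
## (inst/extdata/synthetic_orf1_parents.fasta) together with a coiled coil
## annotation and a mosaic-variant catalogue. The pair is not a genomic
## sequence: it is a constructed 338-residue protein pair whose difference
## structure reproduces the documented design of the modern-vs-resuscitated-
## ancestral mosaic study system -- 42 differences overall, 30 inside the
## 14-heptad coiled coil (residues 52-152, stammer in heptad 6), a
## negatively epistatic quartet at 105/107/108/111 in heptads 8-9, the
## epistatic I77L site, 4 N-terminal-domain differences and 8 in the
## C-terminal half. It exists so that the difference-accounting operations
## can be exercised end to end without genome-derived data.

#' Load the synthetic ORF1p reference system
#'
#' Reads the packaged synthetic modern/ancestral parent pair, the coiled
#' coil annotation and the mosaic-variant catalogue, assembles every
#' variant sequence via [build_mosaic()], and returns the full study
#' system. All sequences are synthetic stand-ins with the documented
#' difference structure (see the package vignette).
#'
#' @return List with elements:
#'   * `modern`, `ancestral`: parent protein strings (length 338);
#'   * `annotation`: [coiled_coil_annotation()] (residues 52-152, 14
#'     heptads, stammer in heptad 6);
#'   * `register`: per-residue heptad table from [assign_register()];
#'   * `regions`: named list of `c(start, end)` region intervals
#'     (`region1`, `region2`, `region3`, `cc`, `ntd`, `cterm`);
#'   * `variants`: data.frame with `name`, `composition`, `substitutions`,
#'     `activity_pct`, `expression_tested`, `sequence`, `activity_class`.
#' @export
orf1_synthetic_reference <- function() {
  ext <- function(f) system.file("extdata", f, package = "ccspace",
                                 mustWork = TRUE)
  parents <- read_alignment(ext("synthetic_orf1_parents.fasta"), "protein")
  modern <- paste0(parents["modern_111p", ], collapse = "")
  ancestral <- paste0(parents["ancestral_555p", ], collapse = "")

  meta <- yaml::read_yaml(ext("synthetic_orf1_annotation.yaml"))
  annotation <- coiled_coil_annotation(meta$cc_start, meta$cc_end,
                                       meta$n_heptads, meta$stammer_heptad)
  regions <- lapply(meta$regions, function(r) c(r[[1]], r[[2]]))

  variants <- read_variant_table(ext("synthetic_variants.tsv"))
  comp_df <- function(comp_str) {
    parents <- strsplit(comp_str, ",", fixed = TRUE)[[1]]
    data.frame(start = vapply(regions[c("region1", "region2", "region3")],
                              `[`, numeric(1), 1L),
               end = vapply(regions[c("region1", "region2", "region3")],
                            `[`, numeric(1), 2L),
               parent = parents, stringsAsFactors = FALSE)
  }
  variants$sequence <- vapply(seq_len(nrow(variants)), function(i)
    build_mosaic(modern, ancestral, comp_df(variants$composition[i]),
                 variants$substitutions[i]),
    character(1))
  variants$activity_class <- classify_activity(variants$activity_pct)

  list(modern = modern, ancestral = ancestral, annotation = annotation,
       register = assign_register(annotation), regions = regions,
       variants = variants)
}
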